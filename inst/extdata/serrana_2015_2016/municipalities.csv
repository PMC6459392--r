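id,name,eligible_population,urban_fraction,fixed_units,machine_years_observed,exams_realized
bom_jardim,Bom Jardim,2675,0.62,0,0,0
cachoeiras_de_macacu,Cachoeiras de Macacu,5658,0.85,3,6,0
cantagalo,Cantagalo,2174,0.68,0,0,441
carmo,Carmo,1969,0.77,1,1,70
cordeiro,Cordeiro,2405,0.92,1,2,4535
duas_barras,Duas Barras,1021,0.52,0,0,0
guapimirim,Guapimirim,4822,0.95,2,4,0
macuco,Macuco,619,0.83,0,0,0
nova_friburgo,Nova Friburgo,23604,0.87,8,12,8856
petropolis,Petropolis,37724,0.95,4,8,15725
santa_maria_madalena,Santa Maria Madalena,1145,0.66,0,0,0
sao_jose_do_vale_do_rio_preto,Sao Jose do Vale do Rio Preto,1923,0.36,1,2,1532
sao_sebastiao_do_alto,Sao Sebastiao do Alto,982,0.48,0,0,0
sumidouro,Sumidouro,1345,0.34,0,0,0
teresopolis,Teresopolis,18929,0.89,2,4,8156
trajano_de_morais,Trajano de Morais,1103,0.57,0,0,0
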