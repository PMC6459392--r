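id_a,id_b,distance_km
petropolis,teresopolis,40
petropolis,sao_jose_do_vale_do_rio_preto,50
teresopolis,sao_jose_do_vale_do_rio_preto,45
teresopolis,guapimirim,35
guapimirim,cachoeiras_de_macacu,25
teresopolis,nova_friburgo,75
nova_friburgo,cachoeiras_de_macacu,55
nova_friburgo,bom_jardim,25
bom_jardim,duas_barras,25
duas_barras,sumidouro,30
teresopolis,sumidouro,60
sumidouro,carmo,35
carmo,cantagalo,30
cantagalo,cordeiro,15
cordeiro,macuco,12
cordeiro,bom_jardim,35
macuco,trajano_de_morais,30
trajano_de_morais,santa_maria_madalena,25
cantagalo,sao_sebastiao_do_alto,25
sao_sebastiao_do_alto,trajano_de_morais,20
nova_friburgo,cordeiro,50
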