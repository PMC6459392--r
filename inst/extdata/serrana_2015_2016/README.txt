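serrana_2015_2016 fixture
=========================

municipalities.csv — observed screening statistics of the 16 municipalities
of the serrana region of Rio de Janeiro state for the 2015-2016 biennium:
eligible female population, installed fixed mammography units, machine-years
of observed operation (possible exams / 5069), and exams realized (counted
at the performing municipality). urban_fraction values are census-style
defaults; the coverage accounting does not depend on them.

edges.csv — SYNTHETIC inter-municipality road distances (km). The source
statistics include no distance table; this one encodes a plausible
highway-adjacency topology of the region. Distances affect travel overhead
in simulations, not the capacity or coverage accounting.
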