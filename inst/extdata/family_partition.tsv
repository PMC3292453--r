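# Published shared/unique family partition over the 1,819-family library.
# Genome A = the selfing species (A. thaliana), B = the outcrossing species
# (A. lyrata). "absent" = library families with no detected copy (RU191).
status	n_families
shared	1447
unique_A	26
unique_B	345
absent	1
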