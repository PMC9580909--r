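#traitguilds-model v1
#response: minimum doubling time
#transform: log
#units: hours
#statistic: MILC codon-usage bias of ribosomal protein genes vs genome background
#provenance: synthetic example coefficients for demonstration and testing only; not trained on growth-rate data
feature	weight
(intercept)	1.5
cub_milc	-1.2
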