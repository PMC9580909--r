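#traitguilds-model v1
#response: optimal growth temperature
#transform: identity
#units: celsius
#provenance: synthetic example coefficients for demonstration and testing only; not trained on growth-temperature data
feature	weight
(intercept)	-20.0
frac_ivywrel	120.0
genome_gc	10.0
frac_charged	20.0
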