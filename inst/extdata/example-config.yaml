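# Example pipeline configuration. The methylation_cutoff of 0.15 is a
# placeholder for demonstration only: the clinically calibrated
# dichotomization cutoff is assay-specific and must be chosen per assay.
seed: 1
simulate: true
methylation_cutoff: 0.15
age_breaks:
- 45
- 55
delta_convention: absolute_points
delta_threshold: 50
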