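# Ecological-status class boundaries for the EQR fish index, by river type/site.
# `default` is the generic 5-class grid; site entries are fixture choices
# consistent with the printed seasonal class pattern of the three Rhone-basin
# monitoring sites (the Good boundary at Jons lies in (0.65, 0.68]).
default: {high: 0.80, good: 0.60, moderate: 0.40, poor: 0.20}
Ain:     {high: 0.90, good: 0.70, moderate: 0.40, poor: 0.20}
Jons:    {high: 0.90, good: 0.66, moderate: 0.40, poor: 0.20}
Tier:    {high: 0.90, good: 0.70, moderate: 0.40, poor: 0.20}
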