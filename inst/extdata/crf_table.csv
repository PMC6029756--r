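stratum_type,stratum,pct,ci_low,ci_high
cause,non-accidental,0.24,0.13,0.35
cause,cardiovascular,0.27,0.10,0.44
cause,respiratory,0.18,-0.11,0.47
age,5-64,0.13,-0.23,0.48
age,65-74,0.19,0.03,0.34
age,75+,0.42,0.21,0.64
season,warm,0.20,0.08,0.31
season,cold,0.43,0.21,0.65
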