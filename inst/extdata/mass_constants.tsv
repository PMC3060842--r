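# Physical mass constants in daltons (Da), monoisotopic unless noted.
# Sources: CODATA 2018 (proton), IUPAC standard atomic masses (molecules,
# combined by summing atomic values).
name	value	note
proton	1.007276466879	CODATA proton mass
hydrogen	1.0078250319	H atom (1H)
water_mono	18.0105646859	H2O monoisotopic
water_avg	18.01528	H2O average
nh3	17.0265491009	ammonia, c-ion offset and NH3 neutral loss
co	27.9949146221	carbon monoxide, a/x-ion offset
h2	2.0156500638	two hydrogen atoms, x-ion offset
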