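# Synthetic enrichment-direction reference table (constructed example,
# not derived from any published dataset). Mimics the format of an
# external human-disease enrichment comparison: one row per gene set,
# sign is + (positively enriched), - (negatively enriched) or ns.
set	sign
planted_set_01	+
planted_set_02	+
planted_set_03	+
planted_set_04	+
planted_set_05	-
decoy_set_001	ns
decoy_set_002	ns
decoy_set_003	-
decoy_set_004	+
decoy_set_005	ns
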