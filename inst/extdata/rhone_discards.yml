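# Example MOTU discard policy for the Rhone survey. The reasons are
# basin-specific (farm effluent, stocking at the opening of the fishing
# season, DNA transported downstream from lakes); they do not generalise to
# other basins and this file is shipped as a documented example, not a default.
- taxon: Cypr_2
  reason: farmed-only
- taxon: Onc_myk
  reason: stocking
- taxon: Cor_spp
  reason: lentic-transport
- taxon: Sal_alp
  reason: lentic-transport
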