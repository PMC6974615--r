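# Reference population figures used for extrapolating per-100,000 prevalence
# bounds to person counts. The worldwide 2017 figure is the denominator of the
# indirect point-prevalence estimate. The EU figure is a user-editable default
# (Eurostat, EU-28, 2017); the USA figures back the count-form national
# definition conversion.
- region: worldwide
  year: 2017
  size: 7550000000.0
- region: eu
  year: 2017
  size: 511500000.0
- region: usa
  year: 1983
  size: 232558140.0
- region: usa
  year: 2017
  size: 325700000.0
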