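# Geography normalisation table: raw area labels (case-insensitive) mapped to
# the three analysis regions. Labels not listed anywhere normalise to "other".
# Europe means the EU member states (2018 membership) plus Russia, Turkey and
# Iceland.
worldwide:
  - Worldwide
  - World
europe:
  - Europe
  - European Union
  - EU
  - Austria
  - Belgium
  - Bulgaria
  - Croatia
  - Cyprus
  - Czech Republic
  - Czechia
  - Denmark
  - Estonia
  - Finland
  - France
  - Germany
  - Greece
  - Hungary
  - Ireland
  - Italy
  - Latvia
  - Lithuania
  - Luxembourg
  - Malta
  - Netherlands
  - Poland
  - Portugal
  - Romania
  - Slovakia
  - Slovenia
  - Spain
  - Sweden
  - United Kingdom
  - Russia
  - Russian Federation
  - Turkey
  - Iceland
usa:
  - USA
  - US
  - United States
  - United States of America
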