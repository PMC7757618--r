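# The six WHO regions used for aggregation. Country membership is supplied
# by the user (add `countries:` lists per region); only the labels are fixed.
regions:
  - label: Africa
  - label: Americas
  - label: Eastern Mediterranean
  - label: Europe
  - label: South Asia
  - label: East Asia and Pacific
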