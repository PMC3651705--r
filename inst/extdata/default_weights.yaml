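baseline:
  tonsil:
    iv: 0.4
    local: 0.4
    oral: 0.4
  esophagus:
    iv: 0.4
    local: 0.4
    oral: 0.4
  stomach:
    iv: 0.4
    local: 0.4
    oral: 0.4
  skin:
    iv: 0.4
    local: 0.4
    oral: 0.4
  muscle:
    iv: 0.4
    local: 0.4
    oral: 0.4
  spleen:
    iv: 0.4
    local: 0.4
    oral: 0.4
  thymus:
    iv: 0.4
    local: 0.4
    oral: 0.4
  lymph_node:
    iv: 0.4
    local: 0.4
    oral: 0.4
  testis:
    iv: 0.4
    local: 0.4
    oral: 0.4
  prostate:
    iv: 0.4
    local: 0.4
    oral: 0.4
  breast:
    iv: 0.4
    local: 0.4
    oral: 0.4
  ovary:
    iv: 0.4
    local: 0.4
    oral: 0.4
  placenta:
    iv: 0.4
    local: 0.4
    oral: 0.4
  lung:
    iv: 0.4
    local: 0.4
    oral: 0.4
  brain:
    iv: 0.2
    local: 0.2
    oral: 0.2
  heart:
    iv: 0.2
    local: 0.2
    oral: 0.2
  colon:
    iv: 0.4
    local: 0.4
    oral: 0.1
  small_intestine:
    iv: 0.4
    local: 0.4
    oral: 0.1
  liver:
    iv: 0.1
    local: 0.1
    oral: 0.1
  kidney:
    iv: 0.1
    local: 0.1
    oral: 0.1
gender:
  testis: male_only
  prostate: male_only
  breast: female_only
  ovary: female_only
  placenta: female_only
modifiers:
  conservative_factor: 0.75
  aggressive_factor: 1.5
  local_relaxation_factor: 1.2
  target_protection_factor: 0.25
  extra_protection_factor: 0.5
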