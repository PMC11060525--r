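unknown_label: Unknown
aliases:
  Pinus resinosa: Pinus banksiana
  Acer pensylvanicum: Acer rubrum
  Juniperus communis: Juniperus/Thuja
  Thuja occidentalis: Juniperus/Thuja
  Picea glauca: Picea
  Picea rubens: Picea
  Betula alleghaniensis: Betula
  Betula papyrifera: Betula
nodes:
- id: main
  name: Main
  level: 1.0
  architecture: deep
  epochs: 200.0
  fallback: Unknown
  outputs:
  - label: Juniperus/Thuja
  - label: Abies/Picea mix
    child: abies_picea
  - label: Pinus mix
    child: pinus
  - label: Triporate mix
    child: triporate
  - label: Tricolpate mix
    child: tricolpate
  - label: NPP/Minerals
- id: abies_picea
  name: Abies/Picea
  level: 2.0
  architecture: deep
  epochs: 250.0
  fallback: Abies/Picea mix
  outputs:
  - label: Abies balsamea
  - label: Picea
- id: pinus
  name: Pinus
  level: 2.0
  architecture: deep
  epochs: 200.0
  fallback: Pinus mix
  outputs:
  - label: Pinus banksiana
  - label: Pinus strobus
- id: triporate
  name: Triporate
  level: 2.0
  architecture: deep
  epochs: 600.0
  fallback: Triporate mix
  outputs:
  - label: Betula
  - label: Corylus cornuta
  - label: Eucalyptus
  - label: Alnus
    child: alnus
- id: tricolpate
  name: Tricolpate
  level: 2.0
  architecture: deep
  epochs: 550.0
  fallback: Tricolpate mix
  outputs:
  - label: Quercus
  - label: Acer
    child: acer
- id: alnus
  name: Alnus
  level: 3.0
  architecture: shallow
  epochs: 170.0
  fallback: Alnus
  outputs:
  - label: Alnus crispa
  - label: Alnus rugosa
- id: acer
  name: Acer
  level: 3.0
  architecture: deep
  epochs: 280.0
  fallback: Acer
  outputs:
  - label: Acer rubrum
  - label: Acer saccharum
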