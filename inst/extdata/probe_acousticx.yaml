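# Default dual-wavelength LED probe: two 50 x 10 mm LED units flanking a
# 128-element linear transducer, tilted 41.4 degrees toward the imaging
# plane, four alternating element rows per unit (850/750/850/750 nm).
unit_length: 50.0
unit_width: 10.0
tilt_angle: 41.4
unit_standoff: 0.15
inter_unit_gap: 9.56
element_pitch: 1.4
row_pitch: 1.72
rows_per_unit:
  - wavelength: 850
    elements: 36
  - wavelength: 750
    elements: 24
  - wavelength: 850
    elements: 36
  - wavelength: 750
    elements: 24
cone_full_angle: 120.0
pulse_energy:
  "750": 100.0
  "850": 200.0
roi_start_depth: 9.2
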