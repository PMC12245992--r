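# Default configuration: 12-scenario vacuum-assisted extraction sweep on the
# calibrated synthetic anatomy, plus the fetal-head compression calibration.
materials:
  pfm:                      # pelvic floor muscle, transversely isotropic
    c_MPa: 0.0185
    b: 1.1730
    A_MPa: 0.0280
    a: 0.6215
    T0M_MPa: 0.682          # inert while theta = 0
    theta: 0.0              # passive tissue
    D_per_MPa: 0.1          # volumetric penalty: 1/D = 10 MPa
  perineal_body:
    E_kPa: 23.8
    nu: 0.49
  bulbospongiosus:
    E_kPa: 23.8
    nu: 0.49
  anal_sphincter:
    c10_MPa: 0.1
  fetal_head:
    E_MPa: 1.1
    nu: 0.25
viscoelastic:
  matrix:
    B: [1.5, 0.7, 0.5]
    tau: [20, 400, 5000]    # s
  fiber:
    B: [1.2, 0.5, 0.3]
    tau: [0.9, 250, 3500]   # s
protocol:
  contractions_s: [60, 90]
  rests_s: [60, 180]
  pulls: [2, 3, 4]
  engagement_s: 10800       # 3 h prolonged-labor engagement ramp
  total_descent_mm: 100
  dt_s: 1
anatomy:
  head_radius_mm: 47.5
  lambda_eng: 1.3           # engagement pre-stretch, both rings
  area_levator_mm2: 150
  area_urogenital_mm2: 100
calibration:
  E_true_MPa: 1.1
  n_points: 20
  noise_cv: 0.02
  radius_mm: 45
  max_deflection_mm: 5
seed: 1
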