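case1:
  id: case1
  probe_material: silicon
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 1.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case2:
  id: case2
  probe_material: silicon
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 10.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case3:
  id: case3
  probe_material: silicon
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 20.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case4:
  id: case4
  probe_material: polyimide
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 1.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case5:
  id: case5
  probe_material: hypothetical
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 1.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case6:
  id: case6
  probe_material: pvac_nc
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 63.0
  displacement: 1.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case7:
  id: case7
  probe_material: pvac_nc
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 1.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case8:
  id: case8
  probe_material: pvac_nc
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 25.0
  displacement: 20.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
case8_thick63:
  id: case8_thick63
  probe_material: pvac_nc
  probe_length: 1125.0
  probe_width: 125.0
  probe_thickness: 63.0
  displacement: 20.0
  mesh:
    h_near: 4.0
    ratio: 1.3
    h_max: 60.0
    n_through_thickness: 3
  brain_E: 6.0
  solver: direct
  tol: 1.0e-08
  vm_nu_eff: ~
  symmetry: quarter
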