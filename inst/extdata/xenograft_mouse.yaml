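# Canonical configuration of the three-compartment VEGF transport model
# (tumor-bearing mouse, human xenograft).  Loaded with
# vegftrap::load_config(); any subset of these keys may appear in a user
# file and is merged onto the package defaults; unknown keys are
# rejected.
#
# Units: kinetic kon 1/M/s, koff 1/s; permeabilities (transport.k_p)
# cm/s; lymph flow (transport.k_L) cm^3/s per cm^3 tissue; clearance
# and trafficking rates 1/s; secretion rates molecules/cell/s; receptor
# densities molecules/cell; cell densities cells/cm^3; GAG site
# concentrations (sites.gag_uM) uM in region fluid; volumes cm^3;
# growth rates 1/day; dosing mg/kg, g, kDa, s; tumor geometry
# primitives um (see derive_tumor_geometry).
name: xenograft_mouse
network:
  isoforms:
    mouse:
    - mV120
    - mV164
    human:
    - hV121
    - hV165
  heparin_binding:
  - mV164
  - hV165
  compartments:
    normal:
      type: tissue
      fluid:
        trap: yes
        svegfr1: yes
        a2m: no
      matrix_regions:
      - ECM
      - EBM
      - PBM
      surfaces:
        myocyte:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          r1_nrp_coupling: no
          ligated_r1_nrp: no
          sr1_nrp: no
          v_sr1_nrp: no
          trafficking: no
          densities:
            VEGFR1: 10000.0
            VEGFR2: 4500.0
            NRP1: 40000.0
          cells_per_cm3: 63000.0
          cell_type: myocyte
          ref_volume: local
        ec_abluminal:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          r1_nrp_coupling: no
          ligated_r1_nrp: no
          sr1_nrp: no
          v_sr1_nrp: no
          trafficking: no
          densities:
            VEGFR1: 3750.0
            VEGFR2: 300.0
            NRP1: 20000.0
          cells_per_cm3: 7000000.0
          cell_type: ec
          ref_volume: local
    blood:
      type: blood
      fluid:
        trap: yes
        svegfr1: yes
        a2m: yes
      matrix_regions: []
      surfaces:
        ec_luminal_normal:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          r1_nrp_coupling: yes
          ligated_r1_nrp: no
          sr1_nrp: yes
          v_sr1_nrp: no
          trafficking: yes
          densities:
            VEGFR1: 3750.0
            VEGFR2: 300.0
            NRP1: 20000.0
          cells_per_cm3: 1.4e+08
          cell_type: ec
          ref_volume: local
        ec_luminal_tumor:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          r1_nrp_coupling: yes
          ligated_r1_nrp: no
          sr1_nrp: yes
          v_sr1_nrp: no
          trafficking: yes
          densities:
            VEGFR1: 3750.0
            VEGFR2: 5000.0
            NRP1: 35000.0
          cells_per_cm3: 3.7825977e+07
          cell_type: ec
          ref_volume: tumor
    tumor:
      type: tissue
      fluid:
        trap: yes
        svegfr1: yes
        a2m: no
      matrix_regions:
      - ECM
      - EBM
      - PBM
      surfaces:
        tumor_cell:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          - NRP2
          r1_nrp_coupling: yes
          ligated_r1_nrp: yes
          sr1_nrp: yes
          v_sr1_nrp: hb
          trafficking: no
          densities:
            VEGFR1: 1100.0
            VEGFR2: 550.0
            NRP1: 35000.0
            NRP2: 35000.0
          cells_per_cm3: 5.9145756e+08
          cell_type: tumor_cell
          ref_volume: local
        ec_abluminal:
          receptors:
          - VEGFR1
          - VEGFR2
          - NRP1
          r1_nrp_coupling: yes
          ligated_r1_nrp: yes
          sr1_nrp: no
          v_sr1_nrp: no
          trafficking: no
          densities:
            VEGFR1: 3750.0
            VEGFR2: 5000.0
            NRP1: 35000.0
          cells_per_cm3: 3.7825977e+07
          cell_type: ec
          ref_volume: local
kinetics:
- class: V-R1
  kon: 3.0e+07
  koff: 0.001
- class: V-R2
  kon: 1.0e+07
  koff: 0.001
- class: V-N
  kon: 3200000.0
  koff: 0.001
- class: R2N
  kon: 3200000.0
  koff: 0.001
- class: R2Nb
  kon: 1.0e+07
  koff: 0.001
- class: R1N
  kon: 3100000.0
  koff: 0.01
- class: V-GAG
  kon: 420000.0
  koff: 0.01
- class: V-sR1
  kon: 3.0e+07
  koff: 0.0003
- class: sR1-N
  kon: 3200000.0
  koff: 0.001
- class: VsR1-N
  kon: 3200000.0
  koff: 0.001
- class: V-Trap
  kon: 1.0e+07
  koff: 6.0e-06
- class: V-a2Mn
  kon: 1000.0
  koff: 0.01
- class: V-a2Mf
  kon: 100000.0
  koff: 0.01
geometry:
  normal:
    volume: 20.0
    K_av: 0.1
    S_EC: 70.0
    region_avail:
      ECM: 0.065
      EBM: 0.005
      PBM: 0.03
  blood:
    volume: 1.0
  tumor:
    primitives: []
sites:
  gag_uM:
    ECM: 0.75
    EBM: 13.0
    PBM: 13.0
secretion:
  q_muscle: 0.011
  q_EC: 0.009
  q_tumor: 0.009
  q_sR1_EC: 0.006
  split_muscle:
  - 0.08
  - 0.92
  split_EC:
  - 0.1
  - 0.9
  split_tumor:
  - 0.5
  - 0.5
transport:
  k_p:
    normal:
      V: 4.0e-08
      Trap: 3.0e-08
      TrapV: 3.0e-08
      sR1: 1.5e-08
      VsR1: 1.5e-08
    tumor:
      V: 4.0e-07
      Trap: 3.0e-07
      TrapV: 3.0e-07
      sR1: 1.5e-07
      VsR1: 1.5e-07
  k_L:
    normal: 7.1e-07
    tumor: 0.0
  clearance:
    V: 0.00023
    Trap: 1.3e-05
    TrapV: 2.5e-06
    sR1: 0.00066
    a2m: 4.37e-05
  k_deg: 0.0001
trafficking:
  k_int: 0.00028
  k_rec: 0.0005
  k_ins: 0.001
  k_deg_endo: 0.0005
soluble:
  a2m_native_M: 1.4e-06
  a2m_fast_M: 1.4e-08
growth:
  V0: 1.0e-06
  trigger_volume: 0.1
  profile: average
  rate:
    average: 0.8223518
    fast: 1.1512925
dosing:
  body_weight_g: 25.0
  mw_kda: 115.0
  infusion_s: 60.0
solver:
  rtol: 1.0e-08
  atol: 1.0e-21
  method: lsoda
tumor: yes
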