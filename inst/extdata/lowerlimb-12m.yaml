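# Toy right lower limb: pelvis - femur - shank - foot with a ball hip and
# knee/ankle hinges (the subtalar joint and patella are omitted in this
# fixture; the schema supports both).  12 muscle elements span hip and
# knee, including two biarticular hamstring-like elements and two
# quadriceps-like elements with femoral-condyle wrap cylinders.
#
# World frame: x anterior, y left, z up; right side at y < 0.
# Hip XYZ Euler dofs: rx > 0 adduction, ry > 0 extension, rz axial rotation.
# Knee hinge about +y: angle > 0 = flexion.  Ankle about +y: > 0 = plantar.
#
# The pelvis segment lumps the head-arms-trunk and contralateral leg mass
# (boundary load on the pelvis); segment mass fractions for the modelled
# leg follow standard anthropometric tables (femur 0.100, shank 0.0465,
# foot 0.0145 of body mass).
name: lowerlimb-12m
subject_mass: 78.0
subject_height: 1.72
gravity: [0.0, 0.0, -9.81]
segments:
  - name: pelvis
    mass: 65.442
    mass_fraction: 0.839
    com: [-0.03, 0.0, 0.08]
    inertia: [1.5, 1.3, 1.2]
    length: 0.2
  - name: femur_r
    mass: 7.8
    mass_fraction: 0.100
    com: [0.0, 0.0, -0.18]
    inertia: [0.12, 0.12, 0.02]
    length: 0.42
  - name: shank_r
    mass: 3.627
    mass_fraction: 0.0465
    com: [0.0, 0.0, -0.17]
    inertia: [0.05, 0.05, 0.005]
    length: 0.40
  - name: foot_r
    mass: 1.131
    mass_fraction: 0.0145
    com: [0.08, 0.0, -0.03]
    inertia: [0.004, 0.004, 0.001]
    length: 0.22
joints:
  - name: hip_r
    kind: ball
    parent: pelvis
    child: femur_r
    location_in_parent: [0.0, -0.09, -0.05]
    location_in_child: [0.0, 0.0, 0.0]
  - name: knee_r
    kind: hinge
    parent: femur_r
    child: shank_r
    location_in_parent: [0.0, 0.0, -0.42]
    location_in_child: [0.0, 0.0, 0.0]
    axis: [0.0, 1.0, 0.0]
  - name: ankle_r
    kind: hinge
    parent: shank_r
    child: foot_r
    location_in_parent: [0.0, 0.0, -0.40]
    location_in_child: [0.0, 0.0, 0.0]
    axis: [0.0, 1.0, 0.0]
muscles:
  - name: psoas_r
    group: iliopsoas_r
    strength: 1500.0
    nodes:
      - {segment: pelvis, point: [0.07, -0.07, 0.05]}
      - {segment: femur_r, point: [0.015, -0.02, -0.06]}
  - name: iliacus_r
    group: iliopsoas_r
    strength: 1500.0
    nodes:
      - {segment: pelvis, point: [0.06, -0.10, 0.03]}
      - {segment: femur_r, point: [0.015, -0.015, -0.055]}
  - name: glutmax1_r
    group: glutmax_r
    strength: 1800.0
    nodes:
      - {segment: pelvis, point: [-0.08, -0.05, 0.02]}
      - {segment: femur_r, point: [-0.035, -0.035, -0.13]}
  - name: glutmax2_r
    group: glutmax_r
    strength: 1800.0
    nodes:
      - {segment: pelvis, point: [-0.09, -0.07, -0.02]}
      - {segment: femur_r, point: [-0.03, -0.03, -0.18]}
  - name: glutmed1_r
    group: glutmed_r
    strength: 1600.0
    nodes:
      - {segment: pelvis, point: [-0.02, -0.10, 0.06]}
      - {segment: femur_r, point: [0.005, -0.045, -0.015]}
  - name: glutmed2_r
    group: glutmed_r
    strength: 1600.0
    nodes:
      - {segment: pelvis, point: [-0.05, -0.09, 0.06]}
      - {segment: femur_r, point: [-0.005, -0.045, -0.02]}
  - name: adductor1_r
    group: adductors_r
    strength: 1500.0
    nodes:
      - {segment: pelvis, point: [0.03, -0.04, -0.06]}
      - {segment: femur_r, point: [0.0, -0.01, -0.20]}
  - name: adductor2_r
    group: adductors_r
    strength: 1500.0
    nodes:
      - {segment: pelvis, point: [-0.01, -0.03, -0.07]}
      - {segment: femur_r, point: [-0.005, -0.008, -0.25]}
  - name: hamstring_med_r
    group: hamstrings_r
    strength: 2000.0
    nodes:
      - {segment: pelvis, point: [-0.06, -0.06, -0.06]}
      - {segment: shank_r, point: [0.005, -0.015, -0.06]}
    wraps:
      - {between: [1, 2], segment: femur_r, center: [-0.035, -0.02, -0.40],
         axis: [0.0, 1.0, 0.0], radius: 0.035, side: -1}
  - name: hamstring_lat_r
    group: hamstrings_r
    strength: 2000.0
    nodes:
      - {segment: pelvis, point: [-0.06, -0.07, -0.06]}
      - {segment: shank_r, point: [0.005, -0.035, -0.055]}
    wraps:
      - {between: [1, 2], segment: femur_r, center: [-0.035, -0.035, -0.40],
         axis: [0.0, 1.0, 0.0], radius: 0.035, side: -1}
  - name: rectfem_r
    group: quadriceps_r
    strength: 2500.0
    nodes:
      - {segment: pelvis, point: [0.06, -0.08, -0.01]}
      - {segment: shank_r, point: [0.045, -0.01, -0.045]}
    wraps:
      - {between: [1, 2], segment: femur_r, center: [0.01, -0.01, -0.41],
         axis: [0.0, 1.0, 0.0], radius: 0.045, side: 1}
  - name: vastus_r
    group: quadriceps_r
    strength: 3000.0
    nodes:
      - {segment: femur_r, point: [0.025, -0.01, -0.15]}
      - {segment: shank_r, point: [0.045, -0.01, -0.04]}
    wraps:
      - {between: [1, 2], segment: femur_r, center: [0.01, -0.01, -0.41],
         axis: [0.0, 1.0, 0.0], radius: 0.045, side: 1}
markers:
  - {name: RASI, segment: pelvis, point: [0.08, -0.12, 0.00], weight: 10.0, bony: true}
  - {name: LASI, segment: pelvis, point: [0.08, 0.12, 0.00], weight: 10.0, bony: true}
  - {name: RPSI, segment: pelvis, point: [-0.12, -0.05, 0.02], weight: 10.0, bony: true}
  - {name: LPSI, segment: pelvis, point: [-0.12, 0.05, 0.02], weight: 10.0, bony: true}
  - {name: FTH1, segment: femur_r, point: [0.05, -0.03, -0.15], weight: 1.0}
  - {name: FTH2, segment: femur_r, point: [0.02, -0.06, -0.25], weight: 1.0}
  - {name: FTH3, segment: femur_r, point: [0.06, -0.01, -0.30], weight: 1.0}
  - {name: FSH1, segment: shank_r, point: [0.04, -0.02, -0.12], weight: 1.0}
  - {name: FSH2, segment: shank_r, point: [0.01, -0.05, -0.22], weight: 1.0}
  - {name: FSH3, segment: shank_r, point: [0.05, 0.00, -0.30], weight: 1.0}
  - {name: FHEE, segment: foot_r, point: [-0.05, 0.00, -0.02], weight: 1.0}
  - {name: FTOE, segment: foot_r, point: [0.15, -0.01, -0.04], weight: 1.0}
  - {name: FMT5, segment: foot_r, point: [0.08, -0.05, -0.03], weight: 1.0}
femur_frame:
  segment: femur_r
  hip_point: [0.0, 0.0, 0.0]
  knee_point: [0.0, 0.0, -0.42]
  anterior_local: [1.0, 0.0, 0.0]
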