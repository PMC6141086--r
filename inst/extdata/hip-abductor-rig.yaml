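# Hip abductor rig: pelvis and right femur on a ball hip, three gluteus
# medius style abductor elements, each wrapping its own pelvis-fixed
# cylinder lateral to the hip centre.  World: x anterior, y left, z up.
# Right side is y < 0.  Hip dofs (XYZ Euler): rx > 0 adduction,
# ry > 0 extension, rz internal/external rotation.
name: hip-abductor-rig
subject_mass: 78.0
subject_height: 1.72
gravity: [0.0, 0.0, -9.81]
segments:
  - name: pelvis
    mass: 70.2
    mass_fraction: 0.9
    com: [-0.03, 0.0, 0.05]
    inertia: [1.5, 1.3, 1.2]
    length: 0.2
  - name: femur_r
    mass: 7.8
    mass_fraction: 0.1
    com: [0.0, 0.0, -0.18]
    inertia: [0.12, 0.12, 0.02]
    length: 0.42
joints:
  - name: hip_r
    kind: ball
    parent: pelvis
    child: femur_r
    location_in_parent: [0.0, -0.09, -0.05]
    location_in_child: [0.0, 0.0, 0.0]
muscles:
  - name: abd1_r
    group: glutmed_r
    strength: 1200.0
    nodes:
      - {segment: pelvis, point: [0.02, -0.11, 0.06]}
      - {segment: femur_r, point: [0.01, -0.045, -0.04]}
    wraps:
      - {between: [1, 2], segment: pelvis, center: [0.01, -0.115, -0.045],
         axis: [1.0, 0.0, 0.0], radius: 0.035, side: 1}
  - name: abd2_r
    group: glutmed_r
    strength: 1200.0
    nodes:
      - {segment: pelvis, point: [-0.01, -0.10, 0.07]}
      - {segment: femur_r, point: [0.0, -0.05, -0.035]}
    wraps:
      - {between: [1, 2], segment: pelvis, center: [-0.01, -0.115, -0.045],
         axis: [1.0, 0.0, 0.0], radius: 0.035, side: 1}
  - name: abd3_r
    group: glutmed_r
    strength: 1200.0
    nodes:
      - {segment: pelvis, point: [-0.04, -0.095, 0.06]}
      - {segment: femur_r, point: [-0.01, -0.05, -0.03]}
    wraps:
      - {between: [1, 2], segment: pelvis, center: [-0.04, -0.115, -0.045],
         axis: [1.0, 0.0, 0.0], radius: 0.035, side: 1}
markers:
  - {name: RASI, segment: pelvis, point: [0.08, -0.12, 0.00], weight: 10.0, bony: true}
  - {name: LASI, segment: pelvis, point: [0.08, 0.12, 0.00], weight: 10.0, bony: true}
  - {name: RPSI, segment: pelvis, point: [-0.12, -0.05, 0.02], weight: 10.0, bony: true}
  - {name: LPSI, segment: pelvis, point: [-0.12, 0.05, 0.02], weight: 10.0, bony: true}
  - {name: FTH1, segment: femur_r, point: [0.05, -0.03, -0.15], weight: 1.0}
  - {name: FTH2, segment: femur_r, point: [0.02, -0.06, -0.25], weight: 1.0}
  - {name: FTH3, segment: femur_r, point: [0.06, -0.01, -0.30], weight: 1.0}
femur_frame:
  segment: femur_r
  hip_point: [0.0, 0.0, 0.0]
  knee_point: [0.0, 0.0, -0.42]
  anterior_local: [1.0, 0.0, 0.0]
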