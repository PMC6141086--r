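# Planar closed-form fixture: a fixed base and one link on a y-axis hinge
# at the origin.  Link frame: x along the link, com at 0.2 m.  Two
# antagonist muscles from the base to the link, symmetric about the x-y
# plane.  World: x forward, z up, gravity -z.
name: planar-2seg
subject_mass: 7.0
subject_height: 1.0
gravity: [0.0, 0.0, -9.81]
segments:
  - name: base
    mass: 5.0
    com: [0.0, 0.0, 0.1]
    inertia: [0.05, 0.05, 0.05]
    length: 0.3
  - name: link
    mass: 2.0
    com: [0.2, 0.0, 0.0]
    inertia: [0.001, 0.03, 0.03]
    length: 0.4
joints:
  - name: elbow
    kind: hinge
    parent: base
    child: link
    location_in_parent: [0.0, 0.0, 0.0]
    location_in_child: [0.0, 0.0, 0.0]
    axis: [0.0, 1.0, 0.0]
muscles:
  - name: lifter
    group: lifter
    strength: 1000.0
    nodes:
      - {segment: base, point: [0.0, 0.0, 0.3]}
      - {segment: link, point: [0.3, 0.0, 0.0]}
  - name: presser
    group: presser
    strength: 1000.0
    nodes:
      - {segment: base, point: [0.0, 0.0, -0.3]}
      - {segment: link, point: [0.3, 0.0, 0.0]}
markers:
  - {name: B1, segment: base, point: [0.10, 0.00, 0.10], weight: 1.0}
  - {name: B2, segment: base, point: [-0.10, 0.05, 0.00], weight: 1.0}
  - {name: B3, segment: base, point: [0.00, -0.08, 0.15], weight: 1.0}
  - {name: L1, segment: link, point: [0.10, 0.00, 0.05], weight: 1.0}
  - {name: L2, segment: link, point: [0.25, 0.03, 0.00], weight: 1.0}
  - {name: L3, segment: link, point: [0.35, -0.02, 0.02], weight: 1.0}
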