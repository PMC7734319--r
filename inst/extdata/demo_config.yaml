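# Canonical demo configuration.
#
# `memdomain synth --config demo_config.yaml --out-dir demo` writes a
# synthetic ternary bilayer (128 lipids per leaflet, 2000 frames at 1 ns)
# with 26 serotonin-like solutes, plus ground truth; `memdomain report`
# with the same config runs the full analysis pipeline on the files.
#
# The geometry is a thin proxy bilayer: head planes at +/-0.55 nm.  The
# synthetic director field obeys kB T / (K_C q^2) at every generated wave
# vector, and this thickness puts >= 4 fluctuation bins inside the
# 3-thickness wavelength window of the bending-modulus fit at this box
# size (~7.6 nm).  Analyses never read these geometry numbers; regions
# are derived from the density profiles at run time.

synthetic:
  n_lipids_per_leaflet: 128
  n_frames: 2000
  frame_spacing: 1.0        # ns
  temperature: 303
  geometry:
    head_z: 0.55
    backbone_dz: 0.2
    chain_top_dz: 0.25
    box_z: 4.0

analysis:
  stride: ~                 # keep every frame

lipids:
  POPC: &phospholipid
    species: phospholipid
    head_ref_atom: HD
    director_vector: [HD, DE]
    tail_vectors:
      - [T1S, T1E]
      - [T2S, T2E]
    ch_pairs:
      - - [C01, H01A]
        - [C01, H01B]
        - [C02, H02A]
        - [C02, H02B]
        - [C03, H03A]
        - [C03, H03B]
        - [C04, H04A]
        - [C04, H04B]
        - [C05, H05A]
        - [C05, H05B]
        - [C06, H06A]
        - [C06, H06B]
  PSM: *phospholipid
  CHOL:
    species: sterol
    head_ref_atom: HD
    director_vector: [HD, DE]
    tail_vectors:
      - [T1S, T1E]
  SRT:
    species: solute
    probe_atom: O1
    com_atoms: [B1, B2, B3, B4, B5, B6, N1, CP1, CP2, O1]
    ring_atoms:
      benzene: [B1, B2, B3, B4, B5, B6]
      pyrrole: [B1, B2, N1, CP1, CP2]
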