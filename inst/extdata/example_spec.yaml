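# A reduced synthetic two-cohort study specification.
n_train: {EOMG: 6, LOMG: 6, CTRL: 6}
n_val: {EOMG: 4, LOMG: 4, CTRL: 0}
cells_per_donor: {train: 500, val: 500}
n_thymus: {EOMG: 4, LOMG: 1}
thymus_cells_per_donor: 250
donor_logit_sd: 0.3
hyperplasia_link: -1.2
mait_fraction: 0.26
seed: 1
subpop_templates:
  - name: CD8T_naive
    lineage: CD8T
    markers: {CCR7: 3.0, CD45RA: 3.2, CD7: 2.8}
    baseline_freq: 0.09
    effect: {LOMG: 0.5}
    clone_param: 0.97
  - name: CD8T_mait
    lineage: CD8T
    markers: {CD161: 3.2, CD45RA: 0.4, CD7: 0.6, CD26: 3.0, CCR7: 0.4}
    baseline_freq: 0.03
    effect: {LOMG: 0.5}
    clone_param: 0.95
    mait: true
  - name: NK_cd57
    lineage: NK
    markers: {CD57: 3.3, CD16: 3.2, NKG2C: 3.0, CD2: 2.8, NKp30: 2.5}
    baseline_freq: 0.06
    effect: {EOMG: 0.5}
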