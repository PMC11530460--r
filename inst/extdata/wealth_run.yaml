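model:
  states:
  - NOCI
  - CIND
  - Dementia
  - Death
  transitions:
  - 1-2
  - 1-3
  - 1-4
  - 2-1
  - 2-3
  - 2-4
  - 3-4
  covariates:
    wealth:
      levels:
      - lowest
      - middle
      - highest
      transitions:
      - 1-2
      - 2-1
      - 2-3
      - 1-3
      - 3-4
    sex:
      levels:
      - male
      - female
      transitions:
      - 1-2
      - 2-1
      - 1-4
      - 2-4
      - 3-4
    marital:
      levels:
      - married
      - single
      transitions:
      - 1-2
      - 2-1
      - 1-4
      - 2-4
      - 3-4
  age_bands:
  - 50.0
  - 60.0
  - 70.0
  - 80.0
  age_transitions:
  - 1-2
  - 2-1
  - 1-4
  - 2-4
  - 3-4
  log_q0:
    1-2: -1.386294361119891
    1-3: -6.214608098422191
    1-4: -3.912023005428146
    2-1: -1.897119984885881
    2-3: -2.995732273553991
    2-4: -2.813410716760036
    3-4: -1.203972804325936
  beta:
    wealth:
      middle:
        1-2: -0.150822889734584
        2-1: 0.254642218373581
        2-3: -0.020202707317519
        1-3: -0.105360515657826
        3-4: 0.165514438477573
      highest:
        1-2: -0.385662480811985
        2-1: 0.444685821261446
        2-3: -0.301105092783922
        1-3: -0.139262067333508
        3-4: -0.020202707317519
    sex:
      female:
        1-2: 0.048790164169432
        2-1: -0.051293294387551
        1-4: -0.287682072451781
        2-4: -0.287682072451781
        3-4: -0.287682072451781
    marital:
      single:
        1-2: 0.095310179804325
        2-1: -0.105360515657826
        1-4: 0.22314355131421
        2-4: 0.22314355131421
        3-4: 0.095310179804325
  age_offsets:
    '[60,70)':
      1-2: 0.182321556793955
      2-1: -0.105360515657826
      1-4: 0.405465108108164
      2-4: 0.405465108108164
      3-4: 0.182321556793955
    '[70,80)':
      1-2: 0.364643113587909
      2-1: -0.210721031315653
      1-4: 0.810930216216329
      2-4: 0.810930216216329
      3-4: 0.364643113587909
    '[80,Inf)':
      1-2: 0.546964670381864
      2-1: -0.316081546973479
      1-4: 1.216395324324493
      2-4: 1.216395324324493
      3-4: 0.546964670381864
  rate_zero: []
cohort:
  n_subjects: 2000
  wave_times:
  - 0.0
  - 2.0
  - 4.0
  - 6.0
  - 8.0
  - 10.0
  covariates:
    sex:
      male: 0.4426
      female: 0.5574
    marital:
      married: 0.653
      single: 0.347
    education:
      low: 0.278127812781278
      middle: 0.541154115411541
      high: 0.180718071807181
    occupation:
      routine: 0.31023102310231
      intermediate: 0.352435243524352
      managerial: 0.337333733373337
    wealth:
      lowest: 0.328032803280328
      middle: 0.337433743374337
      highest: 0.334533453345335
  age:
    mean: 67.0
    sd: 9.5
    min: 50.0
  initial_state_probs:
  - 0.65
  - 0.33
  - 0.02
  dropout_hazard: 0.08
  seed: 1
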