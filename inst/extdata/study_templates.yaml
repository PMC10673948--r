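# Study-design templates emulating the four avalglucosidase alfa trials'
# dosing regimens and sampling schedules (q2w intravenous dosing; times in
# weeks, sampling offsets in hours after end of infusion, EOI).
study1_lopd_phase1:
  lloq: 0.0125
  arms:
  - label: 5 mg/kg
    "n": 8
    dose: 5
    duration_weeks: 25
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [1, 13, 25], predose: true, eoi: true,
               offsets_h: [1, 2, 4, 8, 12, 16, 24, 32, 48]}
  - label: 10 mg/kg
    "n": 8
    dose: 10
    duration_weeks: 25
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [1, 13, 25], predose: true, eoi: true,
               offsets_h: [1, 2, 4, 8, 12, 16, 24, 32, 48]}
  - label: 20 mg/kg
    "n": 8
    dose: 20
    duration_weeks: 25
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [1, 13, 25], predose: true, eoi: true,
               offsets_h: [1, 2, 4, 8, 12, 16, 24, 32, 48]}
study2_lopd_phase12:
  lloq: 0.0125
  arms:
  - label: 5 to 20 mg/kg
    "n": 6
    dose: 5
    switch: {week: 27, dose: 20}
    duration_weeks: 52
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [27, 51], predose: true, eoi: true,
               offsets_h: [1, 4, 8, 12, 24]}
  - label: 10 to 20 mg/kg
    "n": 6
    dose: 10
    switch: {week: 27, dose: 20}
    duration_weeks: 52
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [27, 51], predose: true, eoi: true,
               offsets_h: [1, 4, 8, 12, 24]}
  - label: 20 mg/kg
    "n": 7
    dose: 20
    duration_weeks: 52
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [27, 51], predose: true, eoi: true,
               offsets_h: [1, 4, 8, 12, 24]}
study3_lopd_phase3:
  lloq: 0.0125
  arms:
  - label: 20 mg/kg
    "n": 51
    dose: 20
    duration_weeks: 49
    demographics: {type: adult, age_min: 18, age_max: 78,
                   wt_mean: 75.9, wt_sd: 20.1, wt_lo: 38, wt_hi: 129}
    sampling: {weeks: [1, 49], predose: true, eoi: true,
               offsets_h: [2, 4, 6, 8]}
    sparse_sampling: {weeks: [13, 25, 37], predose: true, eoi: false,
                      offsets_h: [2]}
study4_iopd_phase2:
  lloq: 0.0125
  arms:
  - label: 20 mg/kg
    "n": 6
    dose: 20
    duration_weeks: 25
    demographics: {type: pediatric, age_min: 1, age_max: 11,
                   wt_mean: 29.2, wt_sd: 15.4, wt_lo: 9.9, wt_hi: 63.5,
                   growth_kg_per_year: 2.5}
    sampling: {weeks: [1, 25], predose: true, eoi: true,
               offsets_h: [2, 4, 6, 8]}
    sparse_sampling: {weeks: [13], predose: true, eoi: false, offsets_h: [2]}
  - label: 40 mg/kg
    "n": 10
    dose: 40
    duration_weeks: 25
    demographics: {type: pediatric, age_min: 1, age_max: 11,
                   wt_mean: 29.2, wt_sd: 15.4, wt_lo: 9.9, wt_hi: 63.5,
                   growth_kg_per_year: 2.5}
    sampling: {weeks: [1, 25], predose: true, eoi: true,
               offsets_h: [2, 4, 6, 8, 12, 16]}
    sparse_sampling: {weeks: [13], predose: true, eoi: false, offsets_h: [2]}
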