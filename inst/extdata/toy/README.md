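# Hand-audited toy claims fixture

Ten synthetic patients, three providers, handcrafted to exercise every
cohort and costing boundary rule. Study window 2018-01-01 to 2019-12-31;
tests run the pipeline with `min_volume = 3`.

Expected stage results (audited by hand):

| patient | fate |
|---------|------|
| P01 | index claim 1 (same-day tie with claim 16, lower id wins), thrombectomy, age 67, LOS 10; costs 10000 + 999 (the tie claim 16 is a second same-day hospitalization: overlapping claims are summed, not deduplicated) + 100 (outpatient claim 2 is at day 95, outside); died day 74 |
| P02 | index claim 2, thrombolysis, age 78, LOS 7; costs 2000 + 500 (claim 12, day 60) + 80; survivor |
| P03 | index claim 3, other, age 57, LOS 5; costs 1000 + 0 (claim 13 admitted day 90, outside the half-open window) + 40; survivor |
| P04 | rejected UNDER18 (age 13) |
| P05 | rejected LATE_INDEX (2019-11-15 + 90 days > study end) |
| P06 | index claim 6, other, age 82, LOS 8; costs 1200 + 400 (claim 14, day 89, inside) + 60 (outpatient claim 6 at day 90 outside); death at day 90 = survivor |
| P07 | index claim 7 (earliest of two I63 admissions), other, age 62, LOS 8; costs 900 + 700 (claim 8 is a second I63 admission at day 61, counts as other hospitalization) + 30; survivor |
| P08 | selected, then removed by the volume filter (PRV3 has 1 < 3 index patients) |
| P09 | index claim 10 (claim 15 admitted before the study window is ignored), other, age 67, LOS 9; costs 950 + 0 + 90; survivor |
| P10 | index claim 11, other, age 69, LOS 0; costs 3000 + 0 + 0; died day 0 |

Totals: 10 patients in, 8 index events, rejects UNDER18=1, LATE_INDEX=1,
LOW_VOLUME=1; final cohort 7 episodes, 2 deaths (P01, P10);
sum of in-window costs = 11099 + 2580 + 1040 + 1660 + 1630 + 1040 + 3000 = 22049.
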