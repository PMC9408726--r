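# Reference fixtures

- `published_model_fit.csv` — the published 28-definition summary for the
  two North Carolina regions: definition descriptors, climatological
  thresholds (degC), flagged-day counts and model AICs. Used for the
  AIC-ranking worked example; the thresholds/AICs themselves are not
  reproducible without the restricted source data.
- `published_hw_ed_by_month.csv` — published monthly heat-wave day and HRI
  emergency-department visit counts by region and year (five summer
  seasons; days overlapping NWS alerts excluded from the HW counts).
- `published_alert_overlap.csv` — study-vs-NWS flagged-day marginals per
  region with the reconstructed number of overlap days. `overlap_days` is
  inferred (not directly published): it is the unique integer making the
  continuity-corrected McNemar statistic match the published values
  (158.15 Coastal, 219.04 Piedmont) given the published marginals.
- `nws_heat_index_chart_computed.csv` — chart-style heat-index reference
  values over T 80–110 degF x RH 40–100%, computed by an independent
  (non-R) implementation of the published NWS Rothfusz/Steadman algorithm
  and rounded to whole degF as in the operational chart. A computed
  stand-in for the printed chart, used as the cross-implementation oracle;
  spot anchors from the printed chart (e.g. 90 degF/70% -> 105 degF,
  96 degF/65% -> 121 degF) agree within 1 degF.
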