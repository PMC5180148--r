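# Configuration for the global-mean temperature case study (1880-2015).
#
# Input: a GISTEMP global monthly mean land-ocean temperature-anomaly table
# (one row per year, columns Jan..Dec, anomalies in 0.01 degC relative to
# the 1951-1980 base period, "***" marking missing months). The file is NOT
# shipped; download it from the NASA GISS surface-temperature analysis site
# and pass it with --input. GISTEMP is revised retroactively, so current
# downloads differ slightly from any fixed publication-era snapshot.
#
# Each calendar month is one system variable (12 variables per yearly time
# step). The size of state below is the published 12-entry vector for this
# analysis, in 0.01 degC, Jan..Dec; the stable period that produced it was
# not published, so the values are supplied explicitly rather than
# re-estimated.
format: gistemp
size_of_state:
  mode: explicit
  values: [35.96, 39.21, 34.14, 31.17, 32.94, 24.68, 24.14, 31.28,
           25.87, 36.43, 27.25, 40.81]
window:
  width: 40      # years; climate changes play out over a few decades
  increment: 1
tightening:
  mode: strict   # whether the original analysis averaged tightening levels
                 # is not recorded; run with 'averaged' to compare
smoothing:
  block: 1       # unsmoothed
summary:
  periods: [[1919, 1978], [1979, 2015]]
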