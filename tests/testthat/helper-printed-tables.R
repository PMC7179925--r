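# Published benchmark confusion matrices with their printed metric cells
# (percent recall/specificity/accuracy, fractional precision, MCC). Used
# to check that the metric suite reproduces every derivable cell at the
# printed precision. One row (the cancer/normal SMO validation row) is
# internally inconsistent in the source (TN larger than the cohort) and
# is therefore omitted.
printed_metric_rows <- function() {
  txt <- "table clf dataset tp fp tn fn recall precision spec acc mcc
stage37 SVC train 219 52 81 46 82.64 0.81 60.9 75.38 0.44
stage37 SVC validation 57 18 16 11 83.82 0.76 47.06 71.57 0.33
stage37 SMO train 244 68 65 21 92.08 0.78 48.87 77.64 0.47
stage37 SMO validation 60 24 10 8 88.24 0.71 29.41 68.63 0.22
stage37 J48 train 180 47 86 85 67.92 0.79 64.66 66.83 0.31
stage37 J48 validation 50 16 18 18 73.53 0.76 52.94 66.67 0.26
stage37 NB train 190 39 94 75 71.7 0.83 70.68 71.36 0.4
stage37 NB validation 47 15 19 21 69.12 0.76 55.88 64.71 0.24
stage37 RF train 225 52 81 40 84.91 0.81 60.9 76.88 0.47
stage37 RF validation 52 18 16 16 76.47 0.74 47.06 66.67 0.24
stage36 SVC train 228 17 116 37 86.04 0.93 87.22 86.43 0.71
stage36 SVC validation 52 10 24 16 76.47 0.84 70.59 74.51 0.45
stage36 SMO train 252 30 103 13 95.09 0.89 77.44 89.2 0.75
stage36 SMO validation 59 16 18 9 86.76 0.79 52.94 75.49 0.42
stage36 J48 train 178 52 81 87 67.17 0.77 60.9 65.08 0.27
stage36 J48 validation 51 17 17 17 75 0.75 50 66.67 0.25
stage36 NB train 239 39 94 26 90.19 0.86 70.68 83.67 0.63
stage36 NB validation 58 15 19 10 85.29 0.79 55.88 75.49 0.43
stage36 RF train 197 32 101 68 74.34 0.86 75.94 74.87 0.48
stage36 RF validation 46 11 23 22 67.65 0.81 67.65 67.65 0.34
external18 SVC train 220 50 83 45 83.02 0.81 62.41 76.13 0.46
external18 SVC external 12 0 3 5 70.59 1.00 100 75 0.51
cancer5 SVC train 396 4 42 4 99.00 0.99 91.3 98.21 0.9
cancer5 SVC validation 97 0 12 3 97.00 1.00 100.00 97.32 0.88
cancer5 SMO train 396 6 40 4 99.00 0.99 86.96 97.76 0.88
cancer5 J48 train 397 9 37 3 99.25 0.98 80.43 97.31 0.85
cancer5 J48 validation 97 3 9 3 97.00 0.97 75.00 94.64 0.72
cancer5 NB train 383 3 43 17 95.75 0.99 93.48 95.52 0.80
cancer5 NB validation 91 0 12 9 91.00 1.00 100.00 91.96 0.72
cancer5 RF train 393 5 41 7 98.25 0.99 89.13 97.31 0.86
cancer5 RF validation 95 0 12 5 95.00 1.00 100 95.54 0.82"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(rep("character", 3), rep("numeric", 4),
                                   rep("character", 5)))
}

# Published PPV/NPV call-count tables (cumulative positive/negative calls
# and correct calls at descending probability cut-offs) with the class
# sizes of the cohorts they were computed on.
printed_ppv_npv <- function() {
  thresholds <- seq(1.00, 0.60, by = -0.05)
  list(
    train = list(
      thresholds = thresholds,
      pos_total = c(16, 136, 170, 199, 219, 233, 244, 254, 261),
      pos_correct = c(16, 131, 161, 188, 207, 221, 227, 235, 240),
      neg_total = c(6, 42, 64, 71, 80, 86, 91, 98, 106),
      neg_correct = c(6, 40, 60, 67, 76, 81, 86, 90, 97),
      ppv = c(100.00, 96.32, 94.71, 94.47, 94.52, 94.85, 93.03, 92.52, 91.95),
      npv = c(100.00, 95.24, 93.75, 94.37, 95.00, 94.19, 94.51, 91.84, 91.51),
      n_pos = 265, n_neg = 133),
    validation = list(
      thresholds = thresholds,
      pos_total = c(0, 28, 42, 47, 54, 58, 62, 65, 70),
      pos_correct = c(0, 25, 36, 39, 45, 48, 52, 53, 56),
      neg_total = c(0, 9, 12, 15, 16, 19, 22, 22, 25),
      neg_correct = c(0, 7, 8, 9, 10, 12, 14, 14, 16),
      ppv = c(0.00, 89.29, 85.71, 82.98, 83.33, 82.76, 83.87, 81.54, 80.00),
      npv = c(0.00, 77.78, 66.67, 60.00, 62.50, 63.16, 63.64, 63.64, 64.00),
      n_pos = 68, n_neg = 34))
}
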