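# all eight model variants, built once per test run
all_variants <- local({
  out <- list()
  for (fam in c("2HT", "SDT"))
    for (v in c("classic", "CL", "RT", "CL_RT"))
      out[[paste(fam, v, sep = "_")]] <- mptdc_model(fam, v)
  out
})

# the classic 2HT dataset with a known exact maximum-likelihood solution:
# h_j = do + (1 - do) g_j and f_j = (1 - dn) g_j invert to
# (do, dn, g) = (.5, .5, (.3, .5, .7)) with a perfect fit
classic_2ht_counts <- matrix(
  c(65, 35,   # .35 old: Hit, Miss
    15, 85,   # .35 new: FA, CR
    75, 25,
    25, 75,
    85, 15,
    35, 65),
  nrow = 6, byrow = TRUE)

# brute-force chi-squared for a 2x2 table via expected counts
chi2_expected_counts <- function(tb) {
  n <- sum(tb)
  e <- outer(rowSums(tb), colSums(tb)) / n
  sum((tb - e)^2 / e)
}
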