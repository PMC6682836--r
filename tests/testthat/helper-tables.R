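# Synthetic labelled feature tables for classifier / CV / selection tests.

synthetic_table <- function(n_per_class = 30, informative = "orientation",
                            sep = 3, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  lab <- rep(c("benign", "malignant"), each = n_per_class)
  tab <- data.frame(lesion_id = sprintf("L%03d", sample(n)),
                    label = lab, stringsAsFactors = FALSE)
  for (f in feature_names()) tab[[f]] <- rnorm(n)
  for (f in informative) tab[[f]] <- tab[[f]] + sep * (lab == "malignant")
  tab
}
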