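# Shared fixtures and independent oracles.

make_profile <- function(id, label, keys) variant_profile(id, label, keys)

# Three-profile cohort from the collection-ranking examples:
# site A in all 3 samples, B in 2, C in 1.
abc_cohort <- function() {
  A <- "1:100:A:T"; B <- "2:200:C:G"; C <- "3:300:G:A"
  list(profiles = list(make_profile("s1", "X", c(A, B, C)),
                       make_profile("s2", "X", c(A, B)),
                       make_profile("s3", "X", A)),
       A = A, B = B, C = C)
}

# Write a VCF from a record data frame (columns chrom,pos,ref,alt + optional
# filter), independent of the package's writer.
write_test_vcf <- function(records, path, filter = "PASS") {
  if (!"filter" %in% names(records)) records$filter <- filter
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", records$chrom,
                     records$pos, records$ref, records$alt, records$filter))
  writeLines(lines, path)
  path
}

# Independent AUC oracle: Mann-Whitney rank-statistic formulation with
# midranks for ties, AUC = (R+ - n+(n+ + 1)/2) / (n+ n-).
rank_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  r <- rank(scores)  # midranks
  npos <- sum(pos); nneg <- sum(!pos)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Central finite-difference gradients of the regularized training objective
# (mean cross-entropy + L2), perturbing every parameter in turn.
numeric_gradients <- function(net, X, Y, lambda, eps = 1e-6) {
  loss_at <- function(n) {
    p <- gdl_forward(n, X)
    mean(cross_entropy(p, Y)) + l2_penalty(n$layers, lambda)
  }
  lapply(seq_along(net$layers), function(t) {
    gw <- net$layers[[t]]$w * 0
    for (i in seq_along(gw)) {
      np <- net; nm <- net
      np$layers[[t]]$w[i] <- np$layers[[t]]$w[i] + eps
      nm$layers[[t]]$w[i] <- nm$layers[[t]]$w[i] - eps
      gw[i] <- (loss_at(np) - loss_at(nm)) / (2 * eps)
    }
    gb <- net$layers[[t]]$b * 0
    for (i in seq_along(gb)) {
      np <- net; nm <- net
      np$layers[[t]]$b[i] <- np$layers[[t]]$b[i] + eps
      nm$layers[[t]]$b[i] <- nm$layers[[t]]$b[i] - eps
      gb[i] <- (loss_at(np) - loss_at(nm)) / (2 * eps)
    }
    list(w = gw, b = gb)
  })
}

# Relative error between analytic and numeric gradient sets.
gradient_rel_error <- function(analytic, numeric) {
  a <- unlist(lapply(analytic, function(l) c(l$w, l$b)))
  n <- unlist(lapply(numeric, function(l) c(l$w, l$b)))
  max(abs(a - n) / pmax(abs(n), 1e-3))
}

# Random tiny classification batch for gradient checks.
random_tiny_problem <- function(seed, n_in = 2, hidden = 3, n_classes = 2,
                                n = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_in), n, n_in)
  Y <- t(sapply(sample(n_classes, n, replace = TRUE), function(i) {
    v <- numeric(n_classes); v[i] <- 1; v
  }))
  net <- gdl_network(n_in, hidden = hidden, classes = paste0("C", 1:n_classes),
                     seed = seed)
  list(net = net, X = X, Y = Y)
}
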