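# In-code fixtures shared across the suite.

# A feature_table built directly from a matrix (bypasses peak-list I/O).
make_feature_table <- function(x, label, encoding = "binary",
                               mode = "digested", role = "train") {
  stopifnot(nrow(x) == length(label))
  structure(list(x = x, label = factor(label,
                                       levels = c("positive", "negative")),
                 encoding = encoding, mode = mode, role = role),
            class = "feature_table")
}

# Linearly separable two-class pair of train/score tables: positives carry
# the first `n_signal` bins, negatives the next `n_signal`, plus noise bins.
make_separable_tables <- function(n_per_class = 10, n_bins = 40,
                                  n_signal = 3, noise_p = 0.2, seed = 42) {
  set.seed(seed)
  build <- function(role) {
    n <- 2 * n_per_class
    x <- matrix(rbinom(n * n_bins, 1, noise_p), n, n_bins)
    colnames(x) <- sprintf("b%03d", seq_len(n_bins))
    label <- rep(c("positive", "negative"), each = n_per_class)
    x[label == "positive", seq_len(n_signal)] <- 1
    x[label == "negative", seq_len(n_signal)] <- 0
    x[label == "negative", n_signal + seq_len(n_signal)] <- 1
    x[label == "positive", n_signal + seq_len(n_signal)] <- 0
    rownames(x) <- sprintf("%s_%02d", substr(role, 1, 2), seq_len(n))
    make_feature_table(x, label, role = role)
  }
  list(train = build("train"), score = build("score"))
}

# Write a peak list CSV into a temp dir and return its path.
write_tmp_peaklist <- function(lines, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  path <- tempfile("pl", tmpdir = dir, fileext = ".csv")
  writeLines(lines, path)
  path
}

# A tiny on-disk dataset: n spots per (class, role), digested-style m/z.
make_tmp_dataset <- function(dir, n = 2, mode = "digested", seed = 7) {
  set.seed(seed)
  design <- expand.grid(i = seq_len(n),
                        label = c("positive", "negative"),
                        role = c("train", "score"),
                        stringsAsFactors = FALSE)
  design$spot_id <- sprintf("%s_%s_%d", design$role, design$label, design$i)
  design$file <- file.path(dir, paste0(design$spot_id, ".csv"))
  for (j in seq_len(nrow(design))) {
    base <- if (design$label[j] == "positive") c(800.1, 1200.4) else c(900.2)
    mz <- c(base, runif(3, 210, 6900))
    write_peaklist(peaklist(mz, runif(length(mz), 10, 100),
                            spot_id = design$spot_id[j], mode = mode),
                   design$file[j])
  }
  spot_manifest(design$spot_id, design$file, design$label, design$role,
                mode = mode)
}

# Brute-force bin assignment: scan every center of the scheme, restrict to
# the containing range, nearest center with midpoint ties toward the lower
# center, tolerance width/2. Independent of assign_bin's arithmetic.
brute_force_assign <- function(mz, scheme) {
  spec <- as.data.frame(scheme)
  centers <- bin_centers(scheme)
  labels <- bin_labels(scheme)
  range_of_center <- attr(scheme, "range_index")
  vapply(mz, function(m) {
    r <- which(m >= spec$start & m < spec$end)
    if (!length(r)) return(NA_character_)
    in_r <- which(range_of_center == r)
    d <- abs(centers[in_r] - m)
    best <- in_r[which(d == min(d))]     # ties: lower center = first
    best <- best[1]
    if (abs(centers[best] - m) <= spec$width[r] / 2) labels[best]
    else NA_character_
  }, character(1))
}
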