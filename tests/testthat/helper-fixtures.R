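# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no data files.

# Random symmetric network with unit diagonal and edges in [-1, 1].
random_network <- function(n, seed = NULL, subject_id = NA, modality = NA) {
  if (!is.null(seed)) set.seed(seed)
  v <- runif(n * (n - 1) / 2, -1, 1)
  r2sn:::r2sn_from_adjacency(unvectorize_upper(v), seq_len(n),
                             subject_id, modality)
}

network_from_edges <- function(v) {
  r2sn:::r2sn_from_adjacency(unvectorize_upper(v))
}

# Feature matrix object from a plain numeric matrix.
fm_from_matrix <- function(m, normalized = FALSE, subject_id = "s",
                           modality = "T1") {
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  structure(
    list(matrix = m, region_ids = seq_len(nrow(m)),
         feature_names = colnames(m), subject_id = subject_id,
         modality = modality, normalized = normalized),
    class = "region_feature_matrix"
  )
}

# A deterministic 4x4x4 single-region fixture: 64 enumerated voxel values.
enumerated_region <- function() {
  vol <- array(0, c(4, 4, 4))
  set.seed(42)
  vals <- round(runif(64, 0, 100), 1)
  vol[] <- vals
  parc <- array(1L, c(4, 4, 4))
  list(volume = vol, parcellation = parc, values = vals)
}

# Minimal analysis table: groups, covariates and a score.
toy_table <- function(n_per_group = 20, means = c(NC = 0, MCI = 0, AD = 0),
                      sd = 1, seed = 1) {
  set.seed(seed)
  g <- rep(names(means), each = n_per_group)
  data.frame(
    subject_id = sprintf("s%03d", seq_along(g)),
    group = g,
    age = rnorm(length(g), 73, 7),
    sex = sample(c("M", "F"), length(g), replace = TRUE),
    global_coupling = rnorm(length(g), means[g], sd),
    stringsAsFactors = FALSE
  )
}

# Direct Pearson correlation written out long-hand, as an independent oracle.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
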