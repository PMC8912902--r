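# fixture builders shared across test files; everything is generated in code

make_cq_df <- function(gene, sample, group, cq, replicate = NULL) {
  n <- max(length(gene), length(sample), length(cq))
  if (is.null(replicate)) replicate <- seq_len(n)
  validate_cq_table(data.frame(gene = gene, sample = sample, group = group,
                               replicate = replicate, cq = cq,
                               stringsAsFactors = FALSE))
}

# a deterministic cq_aggregate from a plain matrix + group map
agg_from_matrix <- function(m, groups) {
  structure(list(cq = m,
                 sd = matrix(0, nrow(m), ncol(m), dimnames = dimnames(m)),
                 flag = matrix("ok", nrow(m), ncol(m), dimnames = dimnames(m)),
                 groups = groups, sd_threshold = 0.2),
            class = "cq_aggregate")
}

# standard 10-gene panel config: 8 stable + 1 group-shift + 1 high-noise gene
panel_cfg <- function(seed, n_g = 7L, delta = 0.8, noise_sd = 0.6,
                      base_sd = 0.1) {
  genes <- paste0("g", 1:10)
  shift <- matrix(0, 10, 2, dimnames = list(genes, c("WT", "KO")))
  shift["g9", ] <- c(-delta / 2, delta / 2)
  bsd <- rep(base_sd, 10)
  bsd[10] <- noise_sd
  cq_sim_config(baseline = stats::setNames(seq(18, 26, length.out = 10), genes),
                group_shift = shift, bio_sd = bsd,
                loading_sd = 0.2, tech_sd = 0.05,
                n_per_group = c(WT = n_g, KO = n_g), seed = seed)
}

# independent brute-force Mann-Whitney oracle: counts pairwise wins from the
# raw values (never touches ranks), enumerates assignments recursively
mw_oracle_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n, n1), 2L, u_of)
  min(1, 2 * min(mean(all_u <= u_obs + 1e-9), mean(all_u >= u_obs - 1e-9)))
}
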