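# Independent brute-force oracles, written against the raw session table
# only (direct array indexing; no package milestone/coefficient code).

# First age at which a behavior code has a positive count / a stage flag
# is TRUE, from the raw data frame of one subject. NA if never.
oracle_first_age <- function(si, col, is_flag = FALSE) {
  si <- si[order(si$age_weeks), , drop = FALSE]
  v <- if (is_flag) as.logical(si[[col]]) else si[[col]] > 0
  ages <- si$age_weeks[v]
  if (length(ages) == 0) NA_real_ else ages[1]
}

# Brute-force recomputation of the per-subject change coefficients:
# direct indexing of the session arrays, mirroring the definitions.
oracle_coefficients <- function(sessions, soc_anchor = "VERB2") {
  out <- list()
  for (id in unique(sessions$subject_id)) {
    si <- sessions[sessions$subject_id == id, , drop = FALSE]
    si <- si[order(si$age_weeks), , drop = FALSE]
    hours <- si$duration_minutes / 60
    tw <- oracle_first_age(si, "WALKING", is_flag = TRUE)
    tl <- oracle_first_age(si, "VERB2")
    ts <- oracle_first_age(si, "SYMB4")
    t_soc <- if (soc_anchor == "VERB2") tl else tw
    dd <- function(code, anchor) {
      if (is.na(anchor)) return(NA_real_)
      i <- which(si$age_weeks == anchor)
      if (length(i) != 1 || i == 1) return(NA_real_)
      r <- si[[code]] / hours
      (r[i] - r[i - 1]) / (si$age_weeks[i] - si$age_weeks[i - 1])
    }
    d_sp2 <- dd("VERB2", tw); d_s2 <- dd("SYMB2", tl); d_s3 <- dd("SYMB3", ts)
    out[[id]] <- data.frame(
      subject_id = id, d_sp2 = d_sp2, d_symb2 = d_s2, d_symb3 = d_s3,
      d_soc_infant = dd("SOC_INFANT", t_soc),
      d_soc_mother = dd("SOC_MOTHER", t_soc),
      rr = d_sp2 - d_s2 + d_s3, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# All permutations of seq_len(n) (n small), for exhaustive permutation
# p-value enumeration.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Exhaustive two-sided permutation p-value for a Pearson correlation.
oracle_perm_p_exact <- function(x, y) {
  pm <- all_perms(length(y))
  r_obs <- abs(stats::cor(x, y))
  rs <- apply(pm, 1, function(ix) abs(stats::cor(x, y[ix])))
  mean(rs >= r_obs - 1e-12)
}
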