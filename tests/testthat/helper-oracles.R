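# Independent oracles and small fixture builders used across the suite.

# Wagner-Fischer dynamic-programming edit distance, written independently of
# the package's character-mapped implementation.
lev_dp <- function(a, b) {
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  if (m && n) {
    for (i in 1:m) {
      for (j in 1:n) {
        cost <- if (a[i] == b[j]) 0L else 1L
        d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                               d[i, j] + cost)
      }
    }
  }
  d[m + 1, n + 1]
}

# plain exhaustive recursion (short inputs only)
lev_rec <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  cost <- if (a[1] == b[1]) 0L else 1L
  min(lev_rec(a[-1], b) + 1L,
      lev_rec(a, b[-1]) + 1L,
      lev_rec(a[-1], b[-1]) + cost)
}

# all token sequences of length 0..max_len over an alphabet
all_seqs <- function(alphabet, max_len) {
  out <- list(character(0))
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), l), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unname(unlist(grid[i, ]))
    }))
  }
  out
}

# minimal hand-built records tibble: all indicator codes 0 unless overridden
rec_tbl <- function(surgeon_id, duration_s, month_index = 1L,
                    overrides = list()) {
  n <- length(duration_s)
  sch <- ddss_schema()
  out <- tibble::tibble(
    record_id = sprintf("%s-%03d", rep_len(surgeon_id, n)[1], seq_len(n)),
    surgeon_id = rep_len(surgeon_id, n),
    month_index = as.integer(rep_len(month_index, n)),
    duration_s = duration_s
  )
  for (ab in sch$abbreviation) {
    out[[ab]] <- if (ab %in% names(overrides)) {
      as.integer(rep_len(overrides[[ab]], n))
    } else 0L
  }
  out$record_id <- sprintf("%s-%03d", out$surgeon_id, seq_len(n))
  ddss:::new_ddss_records(out)
}

# compact two-group clinic used by predictor/pipeline tests: 2 experienced +
# 2 novice surgeons, 3 months tenure, 15 records/month
small_clinic_cfg <- function(seed, homogeneous = FALSE) {
  sg <- surgeon_specs_default()[c(1, 2, 6, 9), ]
  sg$tenure_months <- 3L
  sg$records_per_month <- 15L
  cfg <- default_config(surgeons = sg, seed = seed)
  if (homogeneous) {
    cfg$beta_novice <- cfg$beta_experienced
    ddss:::validate_config(cfg)
  }
  cfg
}
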