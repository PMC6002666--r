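# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic entry points funnel through this so that a
# given seed regenerates bit-identical output regardless of call order.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed from a master seed and a block index, kept
# inside the 32-bit integer range.
derive_seed <- function(seed, block) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(block) * 97) %% 2147483647)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must lie strictly inside (0, 1).", name))
  }
  as.numeric(x)
}

# Convert a presence/absence tibble (family_id + one 0/1 column per strain)
# to a logical incidence matrix, families in rows.
pa_incidence <- function(pa) {
  stopifnot(is.data.frame(pa))
  if (!"family_id" %in% names(pa)) {
    abort("A presence/absence table needs a `family_id` column.")
  }
  strains <- setdiff(names(pa), "family_id")
  if (length(strains) == 0L) abort("No strain columns found.")
  m <- as.matrix(pa[strains])
  storage.mode(m) <- "logical"
  if (anyNA(m)) abort("Presence/absence entries must be 0/1 without missing values.")
  rownames(m) <- pa$family_id
  m
}

pa_strains <- function(pa) setdiff(names(pa), "family_id")
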