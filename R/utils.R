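# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. With seed = NULL the global stream is used.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.perm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an n! x n integer matrix (lexicographic-ish
# recursive construction, cached). Guarded by callers; n <= 9 keeps memory
# modest.
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- all_permutations_impl(n)
  if (n <= 8L) .perm_cache[[key]] <- out
  out
}

all_permutations_impl <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations_impl(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    remap <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(remap[sub], m, n - 1L)
  }
  out
}

# Signed angular difference a - b wrapped to (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# atan2 in degrees mapped to [0, 360)
atan2_deg <- function(dy, dx) {
  (atan2(dy, dx) * 180 / pi) %% 360
}

upper_tri <- function(m) m[upper.tri(m)]
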