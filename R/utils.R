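# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 32-bit child seed from a master seed and stream index.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1000003L * as.integer(index)) %% 2147483563L
}

ratio_name <- function(num, den) paste0(num, "/", den)

# Two-level labels, validated; returns a factor with lexicographically sorted
# levels (the package-wide class order convention).
as_group_labels <- function(y, min_per_class = 2L) {
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (anyNA(y)) stop("group labels must not contain NA")
  tab <- table(y)
  if (length(tab) < 2L) stop("need at least 2 classes, got ", length(tab))
  if (any(tab < min_per_class))
    stop("every class needs >= ", min_per_class, " samples; counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  y
}

# 0-based integer codes for a binary factor
binary_codes <- function(y) {
  y <- as_group_labels(y)
  if (nlevels(y) != 2L)
    stop("exactly 2 classes required, got ", nlevels(y))
  as.integer(y) - 1L
}

# minimal union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(name, " must be a single number in [", lower, ", ", upper, "]")
  x
}
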