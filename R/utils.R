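# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage child seeds fanned out from one top-level seed.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
child_seed <- function(seed, stage) {
  stage_num <- sum(utf8ToInt(as.character(stage)) * 31^(seq_len(nchar(as.character(stage))) %% 7))
  as.integer((as.numeric(seed) * 48271 + stage_num) %% 2147483629)
}

# Resolve a group label to sample ids via an annotation column.
group_members <- function(annotation, label, group_col = "group") {
  annotation <- as_annotation(annotation)
  if (!group_col %in% colnames(annotation))
    stop("annotation has no column '", group_col, "'")
  ids <- annotation$sample_id[annotation[[group_col]] == label]
  if (length(ids) == 0L)
    stop("unknown group label '", label, "' in column '", group_col, "'")
  ids
}

# Column variances without the matrixStats dependency.
row_vars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1)
}
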