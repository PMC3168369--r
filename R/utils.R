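# Internal helpers shared across modules.

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seeds spawned from one master seed; all below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Write a data.frame as a single-header tab-separated table.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locate a column by case-insensitive candidate regexes; first hit wins.
match_column <- function(nms, patterns, what, path) {
  for (p in patterns) {
    hit <- grep(p, nms, ignore.case = TRUE)
    if (length(hit)) return(hit[1L])
  }
  stop(sprintf("could not identify %s column in '%s' (columns: %s)",
               what, path, paste(nms, collapse = ", ")), call. = FALSE)
}
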