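# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count <- function(x) {
  is_scalar_num(x) && x >= 0 && abs(x - round(x)) < 1e-8
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# .Random.seed afterwards so simulations never perturb user code.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}


# first few offenders, comma separated, for error messages
fmt_ids <- function(ids, n = 5L) {
  shown <- utils::head(ids, n)
  extra <- length(ids) - length(shown)
  paste0(paste(shown, collapse = ", "),
         if (extra > 0) sprintf(" (+%d more)", extra))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
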