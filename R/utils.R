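#' @keywords internal
"_PACKAGE"

# UTF-8 TSV with a single header row is the interchange format for every
# table in a runs directory.
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    fileEncoding = "UTF-8")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
}

# Rewrite a file atomically: write to a sibling temp file, then rename.
# Protects runsInfo.txt against truncation if the process dies mid-write.
write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  write_tsv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_json_file <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

# Counter-based per-draw seeding: draw i of a session is keyed by
# mix_seed(session_seed, i), so an interrupted-and-resumed session replays
# exactly the stream an uninterrupted one would produce. Two rounds of the
# L'Ecuyer MLCG (modulus 2^31-85, multiplier 40014); bijective in the index,
# exact in double arithmetic (products < 2^53).
mix_seed <- function(seed, index) {
  m <- 2147483563
  h <- function(x) (x * 40014) %% m
  h(h((seed %% m) + 1) + (index %% m) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "psweep_error") {
  stop(errorCondition(paste0(...), class = c(class, "psweep_error")))
}
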