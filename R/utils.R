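# Shared internal helpers: seed scoping, configuration files, superposition.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; blank lines are
#' skipped. Values that parse as numeric vectors (comma- or space-separated)
#' are returned numeric, everything else as character.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- strsplit(val, "[,[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

# Rigid-body least-squares superposition (Kabsch, via base svd).
# Returns the rotation matrix R and translation t such that
# moving %*% R + t best fits `fixed` (both n x 3, row-matched).
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm); b <- sweep(fixed, 2, cf)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = r, translation = cf - as.numeric(cm %*% r))
}

# Unit conversion constants used across the membrane/mechanics modules.
BAR_A3_TO_KCAL_MOL <- 1.4393e-5   # 1 bar * A^3 in kcal/mol
BAR_A_TO_DYN_CM <- 0.01           # 1 bar * A = 1e-5 N/m = 0.01 dyn/cm
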