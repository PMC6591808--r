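# Motif file parsing. Two dialects are supported:
#   JASPAR: ">MA0001.1 NAME" header then four rows "A [ 4 19 0 ... ]"
#   HOMER:  ">CONSENSUS  name  log-odds-threshold" header then one
#           whitespace-delimited probability row (A C G T) per position.
# Parsed PWMs are probability matrices; JASPAR counts are normalized per
# column at parse time, with no pseudocount (pseudocounts belong to scoring).

PWM_BASES <- c("A", "C", "G", "T")

new_pwm <- function(motif_id, prob) {
  stopifnot(is.matrix(prob), nrow(prob) == 4)
  rownames(prob) <- PWM_BASES
  structure(list(motif_id = motif_id, prob = prob), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", ncol(x$prob), " positions)\n", sep = "")
  print(round(x$prob, 3))
  invisible(x)
}

validate_pwm <- function(pwm, tol = 1e-6) {
  prob <- pwm$prob
  assert_that(ncol(prob) >= 1, paste0("PWM '", pwm$motif_id, "' has no columns"))
  assert_that(all(prob >= 0), paste0("PWM '", pwm$motif_id, "' has negative entries"))
  sums <- colSums(prob)
  if (any(abs(sums - 1) > tol)) {
    abort(paste0("PWM '", pwm$motif_id, "' column(s) not normalized: ",
                 paste(which(abs(sums - 1) > tol), collapse = ", ")))
  }
  invisible(pwm)
}

#' Read position-weight matrices
#'
#' @param path Path to a motif file.
#' @param dialect `"jaspar"` (per-base count rows) or `"homer"` (per-position
#'   probability rows).
#' @return A named list of `pwm` objects (probability-normalized; each column
#'   sums to 1).
#' @export
read_pwm <- function(path, dialect = c("jaspar", "homer")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) abort(paste0("empty motif file: ", path))
  switch(dialect,
    jaspar = parse_jaspar(lines, path),
    homer = parse_homer(lines, path)
  )
}

parse_jaspar <- function(lines, path) {
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort(paste0("no '>' record header found in ", path))
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    h <- headers[i]
    block <- lines[seq(h + 1L, length.out = bounds[i + 1L] - h - 1L)]
    motif_id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    if (length(block) < 4) {
      abort(paste0("truncated JASPAR record '", motif_id, "' at line ", h,
                   ": expected 4 base rows, found ", length(block)))
    }
    counts <- matrix(NA_real_, 4, 0)
    rowlen <- NULL
    rows <- setNames(vector("list", 4), PWM_BASES)
    for (ln in block[1:4]) {
      m <- regmatches(ln, regexec("^\\s*([A-Za-z])\\s*\\[?([^]]*)\\]?\\s*$", ln))[[1]]
      if (length(m) == 0) abort(paste0("unparseable JASPAR row at '", ln, "'"))
      base <- toupper(m[2])
      if (!base %in% PWM_BASES) abort(paste0("unknown base symbol '", base, "' in ", path))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (anyNA(vals)) abort(paste0("non-numeric count in JASPAR row '", ln, "'"))
      if (!is.null(rowlen) && length(vals) != rowlen) {
        abort(paste0("ragged JASPAR record '", motif_id, "': row lengths differ"))
      }
      rowlen <- length(vals)
      rows[[base]] <- vals
    }
    if (any(vapply(rows, is.null, logical(1)))) {
      abort(paste0("JASPAR record '", motif_id, "' missing a base row"))
    }
    counts <- do.call(rbind, rows)
    tot <- colSums(counts)
    if (any(tot <= 0)) {
      abort(paste0("JASPAR record '", motif_id, "' has all-zero count column(s): ",
                   paste(which(tot <= 0), collapse = ", ")))
    }
    out[[motif_id]] <- validate_pwm(new_pwm(motif_id, sweep(counts, 2, tot, "/")))
  }
  out
}

parse_homer <- function(lines, path) {
  headers <- grep("^>", lines)
  if (length(headers) == 0) abort(paste0("no '>' record header found in ", path))
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    h <- headers[i]
    fields <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    motif_id <- if (length(fields) >= 2) fields[2] else fields[1]
    block <- lines[seq(h + 1L, length.out = bounds[i + 1L] - h - 1L)]
    if (length(block) == 0) {
      abort(paste0("truncated HOMER record '", motif_id, "' at line ", h, ": no probability rows"))
    }
    prob <- t(vapply(seq_along(block), function(j) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(block[j]), "\\s+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) {
        abort(paste0("malformed HOMER probability row at line ", h + j,
                     " of ", path, ": '", block[j], "'"))
      }
      vals
    }, numeric(4)))
    out[[motif_id]] <- validate_pwm(new_pwm(motif_id, t(prob)))
  }
  out
}

#' Write PWMs in HOMER probability format
#'
#' @param pwms A list of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_homer <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwms) {
    consensus <- paste0(PWM_BASES[apply(pwm$prob, 2, which.max)], collapse = "")
    writeLines(paste0(">", consensus, "\t", pwm$motif_id, "\t0"), con)
    apply(pwm$prob, 2, function(col) {
      writeLines(paste(format(col, digits = 17, scientific = FALSE, trim = TRUE),
                       collapse = "\t"), con)
    })
  }
  invisible(path)
}
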