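#' Read motifs from JASPAR or MEME-minimal files
#'
#' JASPAR matrices given as counts are normalized per column to
#' probabilities. Parse failures report the offending line number.
#'
#' @param path file path.
#' @param format `"jaspar"` or `"meme"`; default guesses from the content.
#' @return a named list of [pfm] objects.
#' @export
read_motifs <- function(path, format = c("auto", "jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  }
  switch(format,
         jaspar = read_jaspar_lines(lines),
         meme = read_meme_lines(lines))
}

read_jaspar_lines <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR '>' header found (line 1)")
  motifs <- list()
  for (i in seq_along(hdr)) {
    start <- hdr[i]
    end <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    name <- sub("^>\\s*", "", lines[start])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(start + 1L):end]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L) {
      stop("JASPAR matrix for '", name, "' must have 4 rows (line ",
           start, ")")
    }
    rows <- lapply(seq_along(body), function(j) {
      ln <- body[j]
      # strip optional leading base letter and brackets: "A [ 1 2 3 ]"
      stripped <- sub("^\\s*[ACGTacgt]?\\s*\\[?", "", ln)
      stripped <- sub("\\]\\s*$", "", stripped)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(stripped),
                                                   "\\s+")[[1]]))
      if (anyNA(vals)) {
        stop("unparseable JASPAR matrix row (line ", start + j, "): ", ln)
      }
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop("ragged JASPAR matrix for '", name, "' (line ", start + 1L, ")")
    }
    m <- do.call(rbind, rows)
    m <- sweep(m, 2, colSums(m), "/")  # counts or probabilities -> columns sum 1
    motifs[[name]] <- pfm(m, name = name, source = "jaspar")
  }
  motifs
}

read_meme_lines <- function(lines) {
  motif_idx <- grep("^MOTIF\\s+", lines)
  if (length(motif_idx) == 0L) stop("no 'MOTIF' record found in MEME file")
  motifs <- list()
  for (start in motif_idx) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[start])), "\\s+")[[1]][1]
    li <- start + 1L
    while (li <= length(lines) &&
           !grepl("^letter-probability matrix", lines[li])) {
      li <- li + 1L
    }
    if (li > length(lines)) {
      stop("missing 'letter-probability matrix' line for motif '", name,
           "' (after line ", start, ")")
    }
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", lines[li])))
    if (is.na(w)) stop("malformed matrix header (line ", li, "): ", lines[li])
    rows <- matrix(0, nrow = w, ncol = 4)
    for (j in seq_len(w)) {
      ln <- lines[li + j]
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) {
        stop("malformed probability row (line ", li + j, "): ", ln)
      }
      rows[j, ] <- vals
    }
    m <- t(rows)
    # written probabilities are rounded (6 decimals): renormalize columns
    m <- sweep(m, 2, colSums(m), "/")
    motifs[[name]] <- pfm(m, name = name, source = "meme")
  }
  motifs
}

#' Write motifs to a JASPAR or MEME-minimal file
#'
#' Probabilities are written at 6 decimals, so a write/read round trip
#' reproduces them within 1e-6.
#'
#' @param motifs a [pfm], a [build_repeat] result, or a list of either.
#' @param path output file path.
#' @param format `"jaspar"` or `"meme"`.
#' @param background length-4 background written to the MEME header.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path, format = c("jaspar", "meme"),
                         background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (inherits(motifs, "pfm") || inherits(motifs, "repeat_motif")) {
    motifs <- list(motifs)
  }
  motifs <- lapply(motifs, function(m) {
    if (inherits(m, "repeat_motif")) m$composite else m
  })
  fmt <- function(x) formatC(x, digits = 6, format = "f")
  if (format == "jaspar") {
    out <- unlist(lapply(motifs, function(m) {
      c(paste0(">", attr(m, "name")),
        vapply(1:4, function(r) {
          paste0(DNA_BASES[r], " [ ",
                 paste(fmt(unclass(m)[r, ]), collapse = " "), " ]")
        }, character(1)))
    }))
  } else {
    out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(rbind(DNA_BASES, fmt(background)), collapse = " "), "")
    for (m in motifs) {
      out <- c(out,
               paste("MOTIF", attr(m, "name")),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m)),
               apply(unclass(m), 2, function(col) {
                 paste0(" ", paste(fmt(col), collapse = " "))
               }),
               "")
    }
  }
  writeLines(out, path)
  invisible(path)
}
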