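# Phospho-CTD heptad-repeat peptides: parsing, motif bookkeeping, extinction.
#
# Peptide specifications follow the repeat notation used for synthetic CTD
# substrates: heptad units (YSPTSPS) are parenthesised, phosphoserine is
# written "pS", flanking residues sit outside the parentheses, and an
# optional leading "FITC-" or "biotin-" token names an N-terminal label.
# Example: "AS(YSPTpSPS)(YSPTSPS)(YSPTpSPS)YS".

PEPTIDE_ALPHABET <- c("Y", "S", "P", "T", "A", "G")
TYR_EXTINCTION_280 <- 1280  # M^-1 cm^-1 per Tyr at 280 nm

#' Parse a CTD peptide specification string
#'
#' Parses the parenthesised heptad-repeat notation into a `ctd_peptide`
#' object.  Indices are 1-based over the full synthesized sequence including
#' flanking residues; N-terminal labels (FITC-, biotin-) and terminal caps
#' are metadata, not residues.  "pS" is stored as S plus a phospho flag so
#' sequence-level operations see the unmodified letter.
#'
#' @param spec Specification string, e.g. `"AS(YSPTpSPS)YS"`.  Bold/emphasis
#'   markers (`*`) are stripped.  A leading `"FITC-"` or `"biotin-"` token
#'   sets the N-terminal cap.
#' @param name Optional peptide name (defaults to the spec string).
#' @param n_term_cap,c_term_cap Terminal chemistry; `n_term_cap` one of
#'   `"free"`, `"acetyl"`, `"biotin-linker"`, `"FITC-linker"` (inferred from
#'   a leading label token when present), `c_term_cap` one of `"free"`,
#'   `"amide"`.
#' @return A `ctd_peptide`: list with `name`, `sequence` (character vector of
#'   one-letter residues), `phospho_positions` (1-based indices of pSer),
#'   `n_repeats`, `repeat_starts` (1-based index of each unit's Y1),
#'   `n_term_cap`, `c_term_cap`.
#' @examples
#' p <- parse_peptide_spec("AS(YSPTpSPS)YS", name = "NMR-1R")
#' length(p$sequence)     # 11
#' p$phospho_positions    # 7
#' @export
parse_peptide_spec <- function(spec, name = NULL,
                               n_term_cap = NULL, c_term_cap = "free") {
  stopifnot(is.character(spec), length(spec) == 1L)
  raw <- spec
  spec <- gsub("\\*", "", spec)

  label <- "free"
  if (grepl("^FITC-", spec)) {
    label <- "FITC-linker"
    spec <- sub("^FITC-", "", spec)
  } else if (grepl("^biotin-", spec)) {
    label <- "biotin-linker"
    spec <- sub("^biotin-", "", spec)
  }
  if (is.null(n_term_cap)) n_term_cap <- label
  n_term_cap <- match.arg(n_term_cap,
                          c("free", "acetyl", "biotin-linker", "FITC-linker"))
  c_term_cap <- match.arg(c_term_cap, c("free", "amide"))

  chars <- strsplit(spec, "")[[1]]
  seq <- character(0)
  phospho <- integer(0)
  repeat_starts <- integer(0)
  in_unit <- FALSE
  unit_start <- NA_integer_
  unit_no <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (in_unit) stop("nested '(' in peptide spec: ", raw, call. = FALSE)
      in_unit <- TRUE
      unit_no <- unit_no + 1L
      unit_start <- length(seq) + 1L
    } else if (ch == ")") {
      if (!in_unit) stop("unmatched ')' in peptide spec: ", raw, call. = FALSE)
      unit_len <- length(seq) - unit_start + 1L
      if (unit_len != 7L) {
        stop(sprintf("heptad unit %d has %d residues (expected 7) in spec: %s",
                     unit_no, unit_len, raw), call. = FALSE)
      }
      repeat_starts <- c(repeat_starts, unit_start)
      in_unit <- FALSE
    } else if (ch == "p") {
      if (i == length(chars) || chars[i + 1L] != "S") {
        stop("'p' phospho flag must precede 'S' in spec: ", raw, call. = FALSE)
      }
      seq <- c(seq, "S")
      phospho <- c(phospho, length(seq))
      i <- i + 1L  # consume the S
    } else if (ch %in% PEPTIDE_ALPHABET) {
      seq <- c(seq, ch)
    } else {
      stop(sprintf("unknown residue letter '%s' in spec: %s", ch, raw),
           call. = FALSE)
    }
    i <- i + 1L
  }
  if (in_unit) stop("unclosed '(' in peptide spec: ", raw, call. = FALSE)
  if (length(repeat_starts) < 1L) {
    stop("peptide spec contains no parenthesized heptad unit: ", raw,
         call. = FALSE)
  }

  structure(
    list(
      name = if (is.null(name)) raw else name,
      sequence = seq,
      phospho_positions = phospho,
      n_repeats = length(repeat_starts),
      repeat_starts = repeat_starts,
      n_term_cap = n_term_cap,
      c_term_cap = c_term_cap
    ),
    class = "ctd_peptide"
  )
}

#' Serialize a `ctd_peptide` back to its canonical specification string
#'
#' Inverse of [parse_peptide_spec()]: parse -> serialize -> parse is the
#' identity on well-formed specifications.
#'
#' @param p A `ctd_peptide`.
#' @param with_label Prepend the `FITC-`/`biotin-` label token when the
#'   N-terminal cap carries one (default `TRUE`).
#' @return The canonical specification string.
#' @export
format_peptide_spec <- function(p, with_label = TRUE) {
  stopifnot(inherits(p, "ctd_peptide"))
  n <- length(p$sequence)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i %in% p$repeat_starts) {
      unit <- vapply(i:(i + 6L), function(j) {
        if (j %in% p$phospho_positions) paste0("p", p$sequence[j])
        else p$sequence[j]
      }, character(1))
      out <- c(out, "(", unit, ")")
      i <- i + 7L
    } else {
      out <- c(out,
               if (i %in% p$phospho_positions) paste0("p", p$sequence[i])
               else p$sequence[i])
      i <- i + 1L
    }
  }
  label <- switch(p$n_term_cap,
                  "FITC-linker" = "FITC-", "biotin-linker" = "biotin-", "")
  paste0(if (with_label) label else "", paste0(out, collapse = ""))
}

#' @export
print.ctd_peptide <- function(x, ...) {
  cat(sprintf("<ctd_peptide> %s\n", x$name))
  cat(sprintf("  spec:      %s\n", format_peptide_spec(x)))
  cat(sprintf("  residues:  %d, repeats: %d\n",
              length(x$sequence), x$n_repeats))
  cat(sprintf("  phospho:   %s\n",
              if (length(x$phospho_positions)) {
                paste(x$phospho_positions, collapse = ", ")
              } else "none"))
  cat(sprintf("  caps:      N %s / C %s\n", x$n_term_cap, x$c_term_cap))
  invisible(x)
}

#' Locate pSer-Pro binding motifs
#'
#' A pSer-Pro motif is a phosphoserine immediately followed by proline --
#' the recognition element for the WW and PPIase domains of parvulin-class
#' isomerases.  Phosphoserines not followed by Pro are omitted with a
#' warning record.
#'
#' @param p A `ctd_peptide`.
#' @return data.frame with columns `pser` and `pro` (1-based indices),
#'   ordered N to C; zero rows when the peptide has no motif.  Omitted
#'   phosphoserines (no trailing Pro) are recorded in the `"omitted"`
#'   attribute and raise a warning.
#' @examples
#' locate_psp_motifs(parse_peptide_spec("AS(YSPTpSPS)YS"))  # pser 7, pro 8
#' @export
locate_psp_motifs <- function(p) {
  stopifnot(inherits(p, "ctd_peptide"))
  n <- length(p$sequence)
  pser <- p$phospho_positions
  has_pro <- vapply(pser, function(i) i < n && p$sequence[i + 1L] == "P",
                    logical(1))
  omitted <- pser[!has_pro]
  if (length(omitted)) {
    warning(sprintf("phosphoserine(s) at %s not followed by Pro; omitted",
                    paste(omitted, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(pser = pser[has_pro], pro = pser[has_pro] + 1L)
  attr(out, "omitted") <- omitted
  out
}

#' Residue spacing between the outermost pSer-Pro motifs
#'
#' The index difference between the phosphoserines of the first and last
#' motifs.  For an nR peptide phosphorylated on the Ser5 of its terminal
#' repeats this equals 7(n-1); the 5R peptide places 28 residues between
#' its two binding sites.
#'
#' @param p A `ctd_peptide`.
#' @return Integer spacing, or `NA_integer_` when the peptide has fewer than
#'   two motifs (a defined-absent result, deliberately not zero).
#' @export
motif_spacing <- function(p) {
  motifs <- suppressWarnings(locate_psp_motifs(p))
  if (nrow(motifs) < 2L) return(NA_integer_)
  as.integer(motifs$pser[nrow(motifs)] - motifs$pser[1L])
}

#' Molar extinction coefficient at 280 nm
#'
#' Sequence-determined estimate of 1280 M^-1 cm^-1 per Tyr residue; label
#' chromophores (FITC) are excluded from the 280 nm estimate.
#'
#' @param p A `ctd_peptide`.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(p) {
  stopifnot(inherits(p, "ctd_peptide"))
  TYR_EXTINCTION_280 * sum(p$sequence == "Y")
}
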