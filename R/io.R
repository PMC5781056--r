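# Readers and writers for the four external input formats: FASTA sequences,
# PSI-BLAST ASCII PSSMs, SPD3-style structural profiles, and site annotation
# tables; plus the per-lysine feature table.

#' Canonical amino-acid column order
#'
#' The fixed 20-letter ordering used for every PSSM column throughout the
#' package: the PSI-BLAST header order A R N D C Q E G H I L K M F P S T W Y V.
#' All parsed matrices are re-mapped to this order.
#'
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residue letters accepted in input sequences (standard 20 plus ambiguity
# codes and selenocysteine)
SEQ_ALPHABET <- c(AA_ORDER, "X", "B", "Z", "U")

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return a named list of protein records, each a list with elements `id`
#'   (first whitespace-delimited token of the header), `sequence` (uppercased)
#'   and `sites` (empty data frame, filled by [attach_sites()]).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(ss))
  recs <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    bad <- setdiff(strsplit(seqs[[i]], "")[[1]], SEQ_ALPHABET)
    if (length(bad) > 0L) {
      stop("illegal sequence character(s) ", paste(unique(bad), collapse = ","),
           " in record '", ids[[i]], "'")
    }
    recs[[i]] <- protein_record(ids[[i]], seqs[[i]])
  }
  names(recs) <- ids
  recs
}

#' Construct a protein record
#'
#' @param id protein identifier.
#' @param sequence amino-acid sequence (uppercase).
#' @param sites data frame with columns `position` (1-based) and `label`
#'   (+1 succinylated / -1 non-succinylated); may be empty.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence,
                           sites = data.frame(position = integer(),
                                              label = integer())) {
  structure(list(id = id, sequence = sequence, sites = sites),
            class = "protein_record")
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the plain-text matrix PSI-BLAST writes with `-out_ascii_pssm`:
#' header lines, then one row per residue carrying the position, the residue
#' letter, 20 integer log-odds scores and 20 weighted observed percentages
#' (optionally followed by two per-position statistics), then trailing lines.
#'
#' The matrix is returned on a linear-probability scale. With
#' `scale_mode = "percent"` (default) the percentage columns are divided by
#' 100 -- they are the only columns already on a linear scale. With
#' `scale_mode = "logodds"` the log-odds columns are mapped through the
#' logistic function 1/(1 + exp(-s)) instead.
#'
#' @param path path to the PSSM file.
#' @param scale_mode `"percent"` or `"logodds"`.
#' @param protein_id identifier to attach; defaults to the file name without
#'   its extension.
#' @return a `pssm_matrix`: list with `protein_id` and `values`, an L x 20
#'   numeric matrix with columns in [AA_ORDER], all entries in \[0, 1\].
#' @export
read_pssm <- function(path, scale_mode = c("percent", "logodds"),
                      protein_id = sub("\\.[^.]*$", "", basename(path))) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  col_order <- AA_ORDER
  rows <- list()
  row_res <- character()
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) == 0L || tok[[1]] == "") next
    # column-order header: 40 single-letter tokens (two blocks of 20)
    if (length(tok) >= 40L && all(tok[1:40] %in% AA_ORDER) &&
        !grepl("^[0-9]", tok[[1]])) {
      col_order <- tok[1:20]
      next
    }
    if (!grepl("^[0-9]+$", tok[[1]])) next          # header/trailing line
    if (length(tok) < 2L || !grepl("^[A-Za-z]$", tok[[2]])) next
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(num) || !(length(num) %in% c(40L, 42L))) {
      stop("PSSM row with unexpected column count at line ", ln, " of ", path)
    }
    rows[[length(rows) + 1L]] <- num[1:40]
    row_res[[length(rows)]] <- toupper(tok[[2]])
  }
  if (length(rows) == 0L) stop("no PSSM data rows found in ", path)
  m <- do.call(rbind, rows)
  vals <- switch(scale_mode,
                 percent = m[, 21:40, drop = FALSE] / 100,
                 logodds = 1 / (1 + exp(-m[, 1:20, drop = FALSE])))
  # re-map to the canonical amino-acid order
  vals <- vals[, match(AA_ORDER, col_order), drop = FALSE]
  colnames(vals) <- AA_ORDER
  if (any(vals < 0 | vals > 1)) {
    stop("PSSM values outside [0, 1] in ", path)
  }
  structure(list(protein_id = protein_id, values = vals, residues = row_res),
            class = "pssm_matrix")
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Percentage columns carry `100 * p`; log-odds columns are derived as
#' `round(10 * log2(p / 0.05))` (background frequency 1/20), which is how the
#' synthetic fixture writer produces realistic-looking files. With
#' `quantize = TRUE` the percentages are rounded to integers as in genuine
#' PSI-BLAST output (lossy at the 0.005 level); with `quantize = FALSE` they
#' keep full precision so a write/read round trip is exact.
#'
#' @param pssm a `pssm_matrix`.
#' @param path output path.
#' @param residues optional residue letters per row (defaults to `X`).
#' @param quantize round percentages to integers (the genuine dialect).
#' @export
write_pssm <- function(pssm, path, residues = NULL, quantize = FALSE) {
  v <- pssm$values
  L <- nrow(v)
  if (is.null(residues)) residues <- pssm$residues
  if (is.null(residues) || length(residues) != L) residues <- rep("X", L)
  lo <- round(10 * log2(pmax(v, 1e-4) / 0.05))
  pc <- if (quantize) round(100 * v) else 100 * v
  pc_fmt <- if (quantize) "%4d" else "%.10g"
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste0("            ", paste(sprintf("%3s", c(AA_ORDER, AA_ORDER)),
                                        collapse = " ")))
  body <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s  ", i, residues[[i]]),
           paste(sprintf("%3d", lo[i, ]), collapse = " "), "  ",
           paste(sprintf(pc_fmt, pc[i, ]), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  writeLines(c(hdr, body, "", "                      K         Lambda"), path)
  invisible(path)
}

#' Read an SPD3-style structural profile
#'
#' Whitespace-delimited table with one row per residue. The default column
#' mapping follows SPIDER2's `.spd3` output: index, residue, secondary
#' structure class, ASA, then the four backbone angles phi, psi, theta, tau,
#' then the coil/strand/helix probabilities P(C), P(E), P(H). Lines starting
#' with `#` are treated as comments.
#'
#' @param path path to the profile.
#' @param columns named integer vector mapping field names
#'   (`asa, phi, psi, theta, tau, pc, pe, ph`) to 1-based column indices.
#' @param protein_id identifier; defaults to the file name sans extension.
#' @return a `structural_profile`: list with `protein_id`, `asa` (length-L,
#'   Angstrom^2), `ss_probs` (L x 3 in the fixed order ph, pe, pc) and
#'   `angles` (L x 4: phi, psi, theta, tau, degrees).
#' @export
read_structural_profile <- function(path,
                                    columns = c(asa = 4, phi = 5, psi = 6,
                                                theta = 7, tau = 8, pc = 9,
                                                pe = 10, ph = 11),
                                    protein_id = sub("\\.[^.]*$", "",
                                                     basename(path))) {
  needed <- c("asa", "phi", "psi", "theta", "tau", "pc", "pe", "ph")
  if (!all(needed %in% names(columns))) {
    stop("column mapping must name all of: ", paste(needed, collapse = ", "))
  }
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- matrix(NA_real_, nrow = length(lines), ncol = length(needed),
                 dimnames = list(NULL, needed))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < max(columns)) {
      stop("missing column(s) at line ", lineno[[i]], " of ", path)
    }
    num <- suppressWarnings(as.numeric(tok[columns[needed]]))
    if (anyNA(num)) stop("non-numeric cell at line ", lineno[[i]], " of ", path)
    rows[i, ] <- num
  }
  if (any(rows[, "asa"] < 0)) stop("negative ASA value in ", path)
  ang <- rows[, c("phi", "psi", "theta", "tau"), drop = FALSE]
  if (any(ang < -180 | ang > 180)) {
    stop("backbone angle outside [-180, 180] in ", path)
  }
  ss <- rows[, c("ph", "pe", "pc"), drop = FALSE]
  if (any(abs(rowSums(ss) - 1) > 0.05)) {
    stop("secondary-structure probabilities do not sum to 1 (+-0.05) in ", path)
  }
  colnames(ss) <- c("ph", "pe", "pc")
  colnames(ang) <- c("phi", "psi", "theta", "tau")
  structure(list(protein_id = protein_id, asa = rows[, "asa"],
                 ss_probs = ss, angles = ang),
            class = "structural_profile")
}

#' Write a structural profile in the SPD3-style layout read by
#' [read_structural_profile()]
#'
#' @param profile a `structural_profile`.
#' @param path output path.
#' @param residues optional residue letters (defaults to `X`).
#' @export
write_structural_profile <- function(profile, path, residues = NULL) {
  L <- length(profile$asa)
  if (is.null(residues) || length(residues) != L) residues <- rep("X", L)
  ss_class <- c("H", "E", "C")[max.col(profile$ss_probs, ties.method = "first")]
  body <- vapply(seq_len(L), function(i) {
    paste(i, residues[[i]], ss_class[[i]],
          sprintf("%.4f", profile$asa[[i]]),
          paste(sprintf("%.4f", profile$angles[i, ]), collapse = " "),
          sprintf("%.6f %.6f %.6f", profile$ss_probs[i, "pc"],
                  profile$ss_probs[i, "pe"], profile$ss_probs[i, "ph"]))
  }, character(1))
  writeLines(c("# index AA SS ASA Phi Psi Theta(i-1=>i+1) Tau(i-2=>i+2) P(C) P(E) P(H)",
               body), path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' Tab- or whitespace-delimited table with columns protein_id, position
#' (1-based), label. Labels are normalised to +1/-1: `+1`, `1`, `pos*`,
#' `succinylated` map to +1; `-1`, `neg*`, `non-succinylated` map to -1.
#'
#' @param path path to the table; a header line is detected and skipped.
#' @return named list mapping protein id to a data frame with columns
#'   `position` and `label`.
#' @export
read_sites <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty sites table: ", path)
  tok1 <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(tok1) >= 2L && is.na(suppressWarnings(as.integer(tok1[[2]])))) {
    lines <- lines[-1]                              # header line
  }
  ids <- character(); pos <- integer(); lab <- integer()
  for (line in lines) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 3L) stop("sites row with fewer than 3 fields: ", line)
    p <- suppressWarnings(as.integer(tok[[2]]))
    if (is.na(p) || p < 1L) stop("non-positive or non-integer position: ", line)
    l <- normalize_label(tok[[3]])
    ids <- c(ids, tok[[1]]); pos <- c(pos, p); lab <- c(lab, l)
  }
  key <- paste(ids, pos)
  if (anyDuplicated(key)) {
    stop("duplicate site annotation(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  out <- split(data.frame(position = pos, label = lab), ids)
  lapply(out, function(d) d[order(d$position), , drop = FALSE])
}

normalize_label <- function(tok) {
  t <- tolower(tok)
  if (t %in% c("+1", "1", "pos", "positive", "succinylated")) return(1L)
  if (t %in% c("-1", "−1", "neg", "negative", "non-succinylated")) return(-1L)
  stop("unknown label token: '", tok, "'")
}

#' Attach site annotations to protein records
#'
#' Sites whose residue is not a lysine (K) are skipped with a warning rather
#' than aborting, to tolerate sequence-version drift between the annotation
#' table and the FASTA file. Positions outside the sequence are errors.
#'
#' @param records list of `protein_record` as from [read_fasta()].
#' @param sites named list as from [read_sites()].
#' @return the records with their `sites` data frames filled in.
#' @export
attach_sites <- function(records, sites) {
  unknown <- setdiff(names(sites), names(records))
  if (length(unknown) > 0L) {
    stop("site annotations for unknown protein(s): ",
         paste(unknown, collapse = ", "))
  }
  for (id in names(sites)) {
    rec <- records[[id]]
    s <- sites[[id]]
    L <- nchar(rec$sequence)
    if (any(s$position > L)) {
      stop("site position beyond sequence length for protein ", id)
    }
    res <- substring(rec$sequence, s$position, s$position)
    not_k <- res != "K"
    if (any(not_k)) {
      warning("skipping ", sum(not_k), " annotated site(s) not at a lysine in ",
              id, " (position ", paste(s$position[not_k], collapse = ","), ")")
      s <- s[!not_k, , drop = FALSE]
    }
    records[[id]]$sites <- s
  }
  records
}

#' Write a per-lysine feature table as TSV
#'
#' One row per lysine: protein_id, position, label, then the feature columns
#' `f0001 ...` zero-padded to a fixed width.
#'
#' @param dataset a `succ_dataset` (see [featurize_dataset()]).
#' @param path output path.
#' @export
write_feature_table <- function(dataset, path) {
  p <- ncol(dataset$X)
  fn <- sprintf("f%04d", seq_len(p))
  df <- data.frame(protein_id = dataset$meta$protein_id,
                   position = dataset$meta$position,
                   label = dataset$y,
                   dataset$X, check.names = FALSE)
  colnames(df)[-(1:3)] <- fn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to the TSV.
#' @return a `succ_dataset`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("protein_id", "position", "label") %in% colnames(df)))
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  new_dataset(X, as.integer(df$label),
              meta = data.frame(protein_id = df$protein_id,
                                position = df$position))
}
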