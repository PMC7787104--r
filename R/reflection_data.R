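# Merged reflection datasets: container, canonicalization, and I/O in two
# formats — the standard binary MTZ layout (self-contained reader/writer, no
# external library available for it here) and a plain tab-separated dialect
# ("# key = value" header lines, then h k l I sigI) for text fixtures.

#' Reflection dataset constructor
#'
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param I,sigI intensities and standard deviations (same arbitrary scale);
#'   negative I is permitted, sigI must be >= 0.
#' @param cell a [unit_cell()].
#' @param laue_symbol Laue/point-group symbol of the merged data.
#' @param spacegroup_symbol optional space-group symbol.
#' @param wavelength optional wavelength in Angstrom.
#' @param flags list; recognised members `amplitudes_converted`,
#'   `french_wilson_suspected` (both default FALSE).
#' @param provenance character vector of applied-correction labels.
#' @param pg optional explicit point group (used for subgroup settings whose
#'   rotations are not derivable from a standard symbol).
#' @param canonicalize map indices to the canonical ASU (default TRUE).
#' @return object of class `refl_dataset`.
#' @export
refl_dataset <- function(hkl, I, sigI, cell, laue_symbol,
                         spacegroup_symbol = NULL, wavelength = NULL,
                         flags = list(), provenance = character(0),
                         pg = NULL, canonicalize = TRUE) {
  hkl <- as.matrix(hkl)
  storage.mode(hkl) <- "integer"
  stopifnot(ncol(hkl) == 3, length(I) == nrow(hkl), length(sigI) == nrow(hkl))
  if (any(rowSums(hkl != 0) == 0)) stop("refl_dataset: zero Miller index present")
  if (any(sigI < 0, na.rm = TRUE)) stop("refl_dataset: negative sigI")
  pg <- if (is.null(pg)) point_group(laue_symbol) else as_point_group(pg)
  if (canonicalize) hkl <- canonical_asu(hkl, pg)
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) {
    stop("refl_dataset: duplicate reflections after mapping to the canonical ASU (",
         sum(duplicated(key)), " duplicates)")
  }
  flags$amplitudes_converted <- isTRUE(flags$amplitudes_converted)
  flags$french_wilson_suspected <- isTRUE(flags$french_wilson_suspected)
  structure(list(hkl = hkl, I = as.numeric(I), sigI = as.numeric(sigI),
                 cell = cell, laue_symbol = laue_symbol, pg = pg,
                 spacegroup_symbol = spacegroup_symbol, wavelength = wavelength,
                 flags = flags, provenance = as.character(provenance)),
            class = "refl_dataset")
}

#' @export
print.refl_dataset <- function(x, ...) {
  d <- resolution(x$hkl, x$cell)$d
  cat(sprintf("refl_dataset: %d unique reflections, Laue %s, %.2f-%.2f Angstrom\n",
              nrow(x$hkl), x$laue_symbol, max(d), min(d)))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

n_refl <- function(ds) nrow(ds$hkl)

# ---------------------------------------------------------------------------
# text dialect

#' Write a reflection dataset
#'
#' `format = "tsv"` writes the documented text dialect (header lines
#' `# key = value`, then tab-separated `h k l I sigI`); `format = "mtz"`
#' writes a standard binary MTZ file (H K L I SIGI columns, provenance stored
#' as history records).
#'
#' @param dataset a [refl_dataset()].
#' @param path output file path.
#' @param format `"tsv"` or `"mtz"`.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(dataset, path, format = c("tsv", "mtz")) {
  format <- match.arg(format)
  if (format == "tsv") write_reflections_tsv(dataset, path) else write_reflections_mtz(dataset, path)
  invisible(path)
}

write_reflections_tsv <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- ds$cell
  writeLines(c(
    sprintf("# cell = %.8g %.8g %.8g %.8g %.8g %.8g", cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
    sprintf("# laue = %s", ds$laue_symbol),
    if (!is.null(ds$spacegroup_symbol)) sprintf("# spacegroup = %s", ds$spacegroup_symbol),
    if (!is.null(ds$wavelength)) sprintf("# wavelength = %.8g", ds$wavelength),
    sprintf("# amplitudes_converted = %s", ds$flags$amplitudes_converted),
    sprintf("# french_wilson_suspected = %s", ds$flags$french_wilson_suspected),
    if (length(ds$provenance)) sprintf("# provenance = %s", paste(ds$provenance, collapse = ";")),
    "h\tk\tl\tI\tsigI"
  ), con)
  df <- data.frame(ds$hkl[, 1], ds$hkl[, 2], ds$hkl[, 3],
                   sprintf("%.10g", ds$I), sprintf("%.10g", ds$sigI))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

read_reflections_tsv <- function(path, column_hints = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body_start <- which(!grepl("^#", lines))[1]
  if (is.na(body_start)) stop("reflection text file has no data section")
  header_cols <- strsplit(lines[body_start], "\t")[[1]]
  tab <- read.table(text = lines[-seq_len(body_start)], sep = "\t",
                    col.names = header_cols, comment.char = "")
  if (is.null(meta$cell)) stop("reflection text file missing '# cell =' header")
  if (is.null(meta$laue)) stop("reflection text file missing '# laue =' header")
  cp <- as.numeric(strsplit(meta$cell, "\\s+")[[1]])
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  cols <- resolve_columns(names(tab), column_hints)
  build_dataset_from_columns(tab, cols, cell, meta$laue,
                             spacegroup = meta$spacegroup,
                             wavelength = if (!is.null(meta$wavelength)) as.numeric(meta$wavelength),
                             provenance = if (!is.null(meta$provenance)) strsplit(meta$provenance, ";")[[1]] else character(0),
                             fw_flag = identical(meta$french_wilson_suspected, "TRUE"),
                             amp_flag = identical(meta$amplitudes_converted, "TRUE"))
}

# choose index/intensity/amplitude columns from available labels
resolve_columns <- function(labels, column_hints = NULL) {
  lab_up <- toupper(labels)
  pick <- function(cands) {
    for (cand in cands) {
      i <- match(toupper(cand), lab_up)
      if (!is.na(i)) return(labels[i])
    }
    NULL
  }
  hints <- column_hints %||% list()
  idx <- list(h = pick(c(hints$h, "H")), k = pick(c(hints$k, "K")), l = pick(c(hints$l, "L")))
  if (any(vapply(idx, is.null, logical(1)))) stop("missing Miller index columns (H, K, L)")
  Icol <- pick(c(hints$I, "I", "IMEAN", "IOBS", "I-OBS"))
  sigIcol <- pick(c(hints$sigI, "SIGI", "SIGIMEAN", "SIGIOBS"))
  Fcol <- pick(c(hints$F, "F", "FP", "FOBS", "F-OBS"))
  sigFcol <- pick(c(hints$sigF, "SIGF", "SIGFP", "SIGFOBS"))
  if (is.null(Icol) && is.null(Fcol)) stop("no intensity and no amplitude column found")
  list(h = idx$h, k = idx$k, l = idx$l, I = Icol, sigI = sigIcol, F = Fcol, sigF = sigFcol)
}

build_dataset_from_columns <- function(tab, cols, cell, laue, spacegroup = NULL,
                                       wavelength = NULL, provenance = character(0),
                                       fw_flag = FALSE, amp_flag = FALSE) {
  hkl <- cbind(tab[[cols$h]], tab[[cols$k]], tab[[cols$l]])
  if (!is.null(cols$I)) {
    I <- tab[[cols$I]]
    sigI <- if (!is.null(cols$sigI)) tab[[cols$sigI]] else rep(0, length(I))
    converted <- amp_flag
  } else {
    # delta-method conversion: I = F^2, sig(I) = 2 F sig(F)
    Fv <- tab[[cols$F]]
    sigF <- if (!is.null(cols$sigF)) tab[[cols$sigF]] else rep(0, length(Fv))
    I <- Fv^2
    sigI <- 2 * abs(Fv) * sigF
    converted <- TRUE
  }
  refl_dataset(hkl, I, sigI, cell, laue,
               spacegroup_symbol = spacegroup, wavelength = wavelength,
               flags = list(amplitudes_converted = converted,
                            french_wilson_suspected = fw_flag),
               provenance = provenance)
}

#' Read a merged reflection file
#'
#' Detects binary MTZ (magic bytes) versus the text dialect. Amplitude-only
#' files are converted to intensities (`I = F^2`, `sigI = 2 F sigF`) and
#' flagged. Indices are mapped to the canonical ASU of the declared Laue
#' group; duplicate unique reflections are a fatal error.
#'
#' @param path input file.
#' @param column_hints optional list with members `h,k,l,I,sigI,F,sigF` naming
#'   the columns to use (defaults `H,K,L,I,SIGI,F,SIGF`).
#' @return a [refl_dataset()].
#' @export
read_reflections <- function(path, column_hints = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) >= 4 && rawToChar(magic) == "MTZ ") {
    read_reflections_mtz(path, column_hints)
  } else {
    read_reflections_tsv(path, column_hints)
  }
}

# ---------------------------------------------------------------------------
# minimal binary MTZ

mtz_pad80 <- function(s) {
  s <- substr(s, 1, 80)
  paste0(s, strrep(" ", 80 - nchar(s)))
}

write_reflections_mtz <- function(ds, path) {
  n <- n_refl(ds)
  labels <- c("H", "K", "L", "I", "SIGI")
  types <- c("H", "H", "H", "J", "Q")
  data <- cbind(ds$hkl[, 1], ds$hkl[, 2], ds$hkl[, 3], ds$I, ds$sigI)
  ncol <- ncol(data)
  cl <- ds$cell
  d <- resolution(ds$hkl, cl)$d
  hist_lines <- c(
    sprintf("HIST flags amplitudes_converted=%s french_wilson_suspected=%s",
            ds$flags$amplitudes_converted, ds$flags$french_wilson_suspected),
    if (!is.null(ds$wavelength)) sprintf("HIST wavelength %.8g", ds$wavelength),
    vapply_chr(as.list(ds$provenance), function(p) paste("HIST provenance", p))
  )
  header <- c(
    "VERS MTZ:V1.1",
    "TITLE refltriage reflection data",
    sprintf("NCOL %8d %12d %8d", ncol, n, 0L),
    sprintf("CELL  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
            cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
    "SORT    1   2   3   0   0",
    sprintf("SYMINF %3d %2d %1s %5d '%s' %s", 1L, 1L, "P", 1L,
            ds$spacegroup_symbol %||% "P 1", ds$laue_symbol),
    "SYMM X,  Y,  Z",
    sprintf("RESO %-12.6f %-12.6f", min(1 / d^2), max(1 / d^2)),
    "VALM NAN",
    sprintf("COLUMN %-30s %1s %17.4f %17.4f    1",
            labels, types, apply(data, 2, min), apply(data, 2, max)),
    "END",
    hist_lines,
    "MTZENDOFHEADERS"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MTZ "), con)
  header_word <- 21L + n * ncol            # 1-based word index of header start
  writeBin(as.integer(header_word), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp (IEEE LE)
  writeBin(raw(80 - 12), con)                        # pad to word 21
  writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  for (rec in header) writeBin(charToRaw(mtz_pad80(rec)), con)
}

read_reflections_mtz <- function(path, column_hints = NULL) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "MTZ ") stop("not an MTZ file: ", path)
  header_word <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", 4))        # machine stamp; IEEE little assumed
  header_at <- (header_word - 1) * 4
  # header records
  seek(con, header_at)
  nrec <- floor((sz - header_at) / 80)
  recs <- vapply(seq_len(nrec), function(i) rawToChar(readBin(con, "raw", 80)), character(1))
  recs <- trimws(recs, which = "right")
  get1 <- function(prefix) {
    hit <- grep(paste0("^", prefix, "\\b"), recs, value = TRUE)
    if (length(hit)) sub(paste0("^", prefix, "\\s*"), "", hit[1]) else NULL
  }
  ncol_line <- get1("NCOL")
  if (is.null(ncol_line)) stop("MTZ header missing NCOL record")
  nn <- as.integer(strsplit(trimws(ncol_line), "\\s+")[[1]])
  ncol <- nn[1]; nref <- nn[2]
  cp <- as.numeric(strsplit(trimws(get1("CELL")), "\\s+")[[1]])
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  syminf <- get1("SYMINF")
  laue <- NULL; sg <- NULL
  if (!is.null(syminf)) {
    msg <- regmatches(syminf, regexec("'([^']*)'\\s*(\\S*)", syminf))[[1]]
    if (length(msg) == 3) { sg <- msg[2]; laue <- if (nzchar(msg[3])) msg[3] else NULL }
  }
  col_recs <- grep("^COLUMN\\b", recs, value = TRUE)
  col_lab <- vapply_chr(as.list(col_recs), function(r) strsplit(trimws(sub("^COLUMN", "", r)), "\\s+")[[1]][1])
  # reflection records
  seek(con, 80)
  raw_dat <- readBin(con, "numeric", n = nref * ncol, size = 4, endian = "little")
  tab <- as.data.frame(matrix(raw_dat, nrow = nref, ncol = ncol, byrow = TRUE))
  names(tab) <- col_lab
  # our own history records
  prov <- character(0); wl <- NULL; fw <- FALSE; amp <- FALSE
  for (r in grep("^HIST\\b", recs, value = TRUE)) {
    body <- trimws(sub("^HIST", "", r))
    if (startsWith(body, "provenance ")) prov <- c(prov, sub("^provenance ", "", body))
    if (startsWith(body, "wavelength ")) wl <- as.numeric(sub("^wavelength ", "", body))
    if (startsWith(body, "flags ")) {
      amp <- grepl("amplitudes_converted=TRUE", body)
      fw <- grepl("french_wilson_suspected=TRUE", body)
    }
  }
  if (is.null(laue)) stop("MTZ header does not declare a Laue symbol")
  cols <- resolve_columns(names(tab), column_hints)
  for (nm in c(cols$h, cols$k, cols$l)) tab[[nm]] <- as.integer(round(tab[[nm]]))
  build_dataset_from_columns(tab, cols, cell, laue, spacegroup = sg,
                             wavelength = wl, provenance = prov,
                             fw_flag = fw, amp_flag = amp)
}

# ---------------------------------------------------------------------------
# expansion to subgroups and re-merging

#' Expand a dataset to a point-group subgroup
#'
#' Each parent-unique reflection generates its full parent orbit; orbit
#' members are mapped to the subgroup's canonical ASU and deduplicated, with
#' intensities and sigmas copied unchanged. No information is lost if the
#' data are perfectly twinned, which is when this operation is wanted.
#'
#' @param dataset a canonical [refl_dataset()].
#' @param sub a `subgroup_descriptor` whose parent matches the dataset's Laue
#'   group.
#' @return expanded [refl_dataset()] in the subgroup setting, with provenance
#'   label `expand:<class label>` appended.
#' @export
expand_to_subgroup <- function(dataset, sub) {
  stopifnot(inherits(dataset, "refl_dataset"), inherits(sub, "subgroup_descriptor"))
  if (!identical(sub$parent, dataset$pg$symbol)) {
    stop("subgroup parent (", sub$parent, ") does not match dataset Laue group (",
         dataset$pg$symbol, ")")
  }
  sub_pg <- as_point_group(sub)
  imgs <- orbit_images(dataset$hkl, dataset$pg)
  n <- n_refl(dataset)
  all_h <- do.call(rbind, imgs)
  all_i <- rep(seq_len(n), times = length(imgs))
  can <- canonical_asu(all_h, sub_pg)
  key <- paste(all_i, can[, 1], can[, 2], can[, 3])
  keep <- !duplicated(key)
  refl_dataset(can[keep, , drop = FALSE], dataset$I[all_i[keep]], dataset$sigI[all_i[keep]],
               dataset$cell, laue_symbol = sub_pg$symbol,
               spacegroup_symbol = dataset$spacegroup_symbol,
               wavelength = dataset$wavelength, flags = dataset$flags,
               provenance = c(dataset$provenance, paste0("expand:", sub$label)),
               pg = sub_pg, canonicalize = FALSE)
}

#' Re-merge an expanded dataset back to a parent point group
#'
#' Inverse of [expand_to_subgroup()] for perfectly consistent copies: maps all
#' indices to the parent canonical ASU and averages duplicates (exact when the
#' expanded copies are untouched).
#'
#' @param dataset expanded [refl_dataset()].
#' @param parent_pg parent [point_group()].
#' @return merged [refl_dataset()] in the parent setting.
#' @export
merge_to_parent <- function(dataset, parent_pg) {
  parent_pg <- as_point_group(parent_pg)
  can <- canonical_asu(dataset$hkl, parent_pg)
  key <- paste(can[, 1], can[, 2], can[, 3])
  grp <- match(key, unique(key))
  # grp values are 1..k in first-occurrence order, matching can[first, ]
  I <- as.numeric(tapply(dataset$I, grp, mean))
  sigI <- as.numeric(tapply(dataset$sigI, grp, mean))
  first <- !duplicated(grp)
  refl_dataset(can[first, , drop = FALSE], I, sigI,
               dataset$cell, laue_symbol = parent_pg$symbol,
               spacegroup_symbol = dataset$spacegroup_symbol,
               wavelength = dataset$wavelength, flags = dataset$flags,
               provenance = c(dataset$provenance, paste0("merge:", parent_pg$symbol)),
               pg = parent_pg, canonicalize = FALSE)
}

#' Screen axial reflections for a systematic absence
#'
#' Screw axes extinguish axial reflections whose index is not divisible by the
#' screw period; this screen reports whether such reflections are measurably
#' present. Verdict is `"unmeasured"` when fewer than 3 screened reflections
#' exist, `"absent"` when their mean I/sig is below 2, else `"present"`.
#'
#' @param dataset a [refl_dataset()].
#' @param axis `"a"`, `"b"` or `"c"`.
#' @param period screw period: 2, 3, 4 or 6.
#' @return list with `n_observed`, `mean_I_over_sig`, `verdict`.
#' @export
score_axial_absences <- function(dataset, axis = c("a", "b", "c"), period = 2) {
  axis <- match.arg(axis)
  stopifnot(period %in% c(2, 3, 4, 6))
  ax_i <- match(axis, c("a", "b", "c"))
  H <- dataset$hkl
  # axial: the two other indices zero (search the full Laue orbit so the ASU
  # representative's sign/permutation does not hide axials)
  imgs <- orbit_images(H, dataset$pg)
  is_axial <- rep(FALSE, nrow(H)); ax_index <- integer(nrow(H))
  for (img in imgs) {
    hit <- rowSums(img[, -ax_i, drop = FALSE] != 0) == 0 & img[, ax_i] > 0
    new_hit <- hit & !is_axial
    ax_index[new_hit] <- img[new_hit, ax_i]
    is_axial <- is_axial | hit
  }
  sel <- is_axial & (ax_index %% period != 0)
  n <- sum(sel)
  if (n < 3) {
    return(list(n_observed = n, mean_I_over_sig = NA_real_, verdict = "unmeasured"))
  }
  ios <- dataset$I[sel] / pmax(dataset$sigI[sel], .Machine$double.eps)
  m <- mean(ios)
  list(n_observed = n, mean_I_over_sig = m,
       verdict = if (m < 2) "absent" else "present")
}
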