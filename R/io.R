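# Formats: FASTA in, PDB 3.3 out/in, profile TSV, run manifests.

#' Read protein sequences from FASTA
#'
#' Plain FASTA parsing with strict validation: sequences are upper-cased,
#' duplicate identifiers rejected, and any letter outside the 20 standard
#' one-letter codes is reported with its record and position.  Alignment
#' gaps (`-`) are only accepted in aligned mode (consensus input).
#'
#' @param path FASTA file.
#' @param aligned Allow `-` gap characters.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (first line is not a header)",
                    call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs))
  allowed <- c(names(AA1), if (aligned) "-")
  for (k in seq_along(seqs)) {
    letters1 <- strsplit(seqs[[k]], "")[[1]]
    bad <- which(!letters1 %in% allowed)
    if (length(bad)) {
      if (letters1[bad[1]] == "-")
        stop("alignment gap at position ", bad[1], " in record '", ids[k],
             "': gapped input is only accepted by the consensus mode",
             call. = FALSE)
      stop("illegal character '", letters1[bad[1]], "' at position ",
           bad[1], " in record '", ids[k], "'", call. = FALSE)
    }
  }
  stats::setNames(as.character(seqs), ids)
}

pdb_atom_line <- function(serial, name, resname, resid, x, y, z, element) {
  # PDB 3.3 fixed columns; atom names of < 4 chars start in column 14
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, resid, x, y, z, 1, 0, element)
}

conformation_pdb_lines <- function(x, serial0 = 0L) {
  at <- x$atoms
  vapply(seq_len(nrow(at)), function(k)
    pdb_atom_line(serial0 + k, at$name[k], AA1[[at$restype[k]]], at$resid[k],
                  at$x[k], at$y[k], at$z[k], at$element[k]), character(1))
}

#' Write a conformation as a PDB file
#'
#' Standard fixed-width ATOM records (PDB 3.3), chain A, 1-based residue
#' numbering.
#'
#' @param x A `conformation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  writeLines(c(conformation_pdb_lines(x), "END"), path)
  invisible(path)
}

#' Write a model archive as a multi-MODEL PDB
#'
#' MODEL/ENDMDL blocks numbered from 1, each carrying a REMARK line with
#' the model's energy; column-exact ATOM records.
#'
#' @param model_set A `model_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_pdb <- function(model_set, path) {
  out <- character(0)
  for (k in seq_along(model_set$models)) {
    out <- c(out,
             sprintf("MODEL     %4d", k),
             sprintf("REMARK 250 ENERGY %12.4f KJ/MOL", model_set$energies[k]),
             conformation_pdb_lines(model_set$models[[k]]),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a peptide structure from PDB
#'
#' Minimal single-chain reader for externally supplied all-atom peptides
#' (first MODEL only); atoms are annotated through the packaged seven-type
#' tables.  Unknown residue or atom names are rejected.
#'
#' @param path PDB file.
#' @param ff Force field.
#' @return A `conformation` (without state indices).
#' @export
read_pdb_conformation <- function(path, ff = load_forcefield()) {
  lines <- readLines(path, warn = FALSE)
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  at <- lines[grepl("^ATOM  ", lines)]
  if (!length(at)) stop("no ATOM records in ", path, call. = FALSE)
  name <- trimws(substr(at, 13, 16))
  resname <- trimws(substr(at, 18, 20))
  resid <- as.integer(substr(at, 23, 26))
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  res1 <- names(AA1)[match(resname, AA1)]
  if (anyNA(res1))
    stop("unknown residue name(s): ",
         paste(unique(resname[is.na(res1)]), collapse = ", "), call. = FALSE)
  resid <- match(resid, sort(unique(resid)))  # renumber 1..n
  keep <- name != "OXT" & !grepl("^[0-9]*H", name) | name == "H"
  name <- name[keep]; res1 <- res1[keep]; resid <- resid[keep]
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  type <- mapply(assign_atom_type, res1, name)
  q <- mapply(assign_charge, res1, name)
  atoms <- tibble::tibble(name = name, element = atom_element(name),
                          resid = resid, restype = res1,
                          type = as.integer(type), q = as.numeric(q),
                          x = x, y = y, z = z)
  atoms$r0 <- ff$types$r0[atoms$type]
  atoms$etr <- ff$types$etr[atoms$type]
  atoms$hydrophobic <- ff$types$hydrophobic[atoms$type]
  seq1 <- paste(res1[!duplicated(resid)], collapse = "")
  structure(list(sequence = seq1, atoms = atoms, dihedrals = NULL,
                 state_indices = NULL,
                 bonds = cbind(i = integer(0), j = integer(0))),
            class = "conformation")
}

#' Write a residue profile as TSV
#'
#' Header line, tab separation, `.` for missing values, no locale
#' formatting.
#'
#' @param profile A `residue_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  for (cc in names(df))
    if (is.numeric(df[[cc]])) df[[cc]] <- formatC(df[[cc]], format = "g")
  df[df == "NA" | is.na(df)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a scan run manifest as JSON
#'
#' Configuration snapshot, per-window seeds and package version:
#' everything needed to re-run any window bit-identically.
#'
#' @param scan A `tmd_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(scan, path) {
  jsonlite::write_json(scan$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
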