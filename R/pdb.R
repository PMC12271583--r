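#' Read a biological-assembly PDB file into an atom table
#'
#' Parses fixed-column ATOM/HETATM records from a PDB (or `.pdb1` biological
#' assembly) file. Assembly files expand the functional multimer over multiple
#' `MODEL` blocks; all models are **concatenated** -- they are assembly copies,
#' not alternative conformers. Waters are dropped by default. When a single
#' atom position carries several alternate-location records, the one with the
#' highest occupancy is kept (ties: first in file).
#'
#' @param path path to a PDB / .pdb1 file.
#' @param include_hetero keep HETATM records (ligands, ions, glycans)?
#'   Default `TRUE`: deposited assemblies fully occupy their maps.
#' @param skip_waters drop water residues (HOH/WAT/DOD)? Default `TRUE`.
#' @param alt_loc_policy `"occupancy"` (keep the highest-occupancy alternate,
#'   default) or `"all"` (keep every record).
#' @return A tibble (the package's `Structure` representation) with columns
#'   `model`, `serial`, `name`, `alt_loc`, `res_name`, `chain`, `res_seq`,
#'   `i_code`, `x`, `y`, `z`, `occupancy`, `b_factor`, `element`,
#'   `is_hetero`; atoms appear in file order. The file stem is attached as
#'   attribute `"source_id"`.
#' @export
read_assembly <- function(path, include_hetero = TRUE, skip_waters = TRUE,
                          alt_loc_policy = c("occupancy", "all")) {
  alt_loc_policy <- match.arg(alt_loc_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  atoms <- parse_pdb_lines(lines)
  if (!include_hetero) atoms <- atoms[!atoms$is_hetero, ]
  if (skip_waters) atoms <- atoms[!atoms$res_name %in% c("HOH", "WAT", "DOD"), ]
  if (alt_loc_policy == "occupancy" && any(atoms$alt_loc != "")) {
    key <- paste(atoms$model, atoms$chain, atoms$res_seq, atoms$i_code,
                 atoms$res_name, atoms$name, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(rows) {
      rows[which.max(atoms$occupancy[rows])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), ]
  }
  if (nrow(atoms) == 0L) {
    stop("no atoms left after filtering: ", path, call. = FALSE)
  }
  out <- tibble::as_tibble(atoms)
  attr(out, "source_id") <- sub("\\.(pdb1?|ent)(\\.gz)?$", "",
                                basename(path))
  out
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  model_of <- rep(1L, length(lines))
  if (length(model_starts)) {
    model_id <- suppressWarnings(as.integer(substr(lines[model_starts], 11, 14)))
    model_id[is.na(model_id)] <- seq_along(model_starts)
    idx <- findInterval(seq_along(lines), model_starts)
    model_of <- ifelse(idx == 0L, 1L, model_id[pmax(idx, 1L)])
  }
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  ln <- lines[is_atom]
  if (!length(ln)) stop("no ATOM/HETATM records found", call. = FALSE)
  ln <- formatC(ln, width = -80) # pad short lines

  num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
  str <- function(a, b) trimws(substr(ln, a, b))

  element <- str(77, 78)
  name <- str(13, 16)
  # derive element from the atom name when column 77-78 is blank
  miss <- element == ""
  if (any(miss)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name[miss])))
    guess <- ifelse(nchar(guess) > 0, substr(guess, 1, 1), "")
    element[miss] <- guess
  }
  occ <- num(55, 60)
  occ[is.na(occ)] <- 1

  xyz <- cbind(num(31, 38), num(39, 46), num(47, 54))
  if (any(!is.finite(xyz))) {
    stop("unparseable coordinates in ATOM/HETATM record", call. = FALSE)
  }
  data.frame(
    model = model_of[is_atom],
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = name,
    alt_loc = str(17, 17),
    res_name = str(18, 20),
    chain = str(22, 22),
    res_seq = suppressWarnings(as.integer(substr(ln, 23, 26))),
    i_code = str(27, 27),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    b_factor = num(61, 66),
    element = toupper(element),
    is_hetero = substr(ln, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
}

#' Write an atom table as a PDB file
#'
#' Emits fixed-column ATOM/HETATM records, wrapping each distinct `model`
#' value in MODEL/ENDMDL blocks when there is more than one. Used by the
#' fixture generator; the output is parseable by [read_assembly()] and by
#' standard structure viewers.
#'
#' @param structure an atom tibble as returned by [read_assembly()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(is.data.frame(structure), nrow(structure) > 0)
  fmt_atom <- function(a, serial) {
    name <- a$name
    # PDB convention: 1-2 letter element names start in column 14
    name_f <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name),
                     sprintf("%-4s", name))
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$is_hetero, "HETATM", "ATOM"),
            serial, name_f, a$alt_loc, a$res_name, a$chain, a$res_seq,
            a$i_code, a$x, a$y, a$z, a$occupancy,
            ifelse(is.na(a$b_factor), 0, a$b_factor), a$element)
  }
  models <- unique(structure$model)
  out <- character(0)
  for (m in models) {
    sub <- structure[structure$model == m, ]
    recs <- fmt_atom(sub, seq_len(nrow(sub)))
    if (length(models) > 1L) {
      recs <- c(sprintf("MODEL     %4d", m), recs, "ENDMDL")
    }
    out <- c(out, recs)
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# residues treated as standard amino acids for backbone atom classes
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

#' Assign atom-type class codes
#'
#' Maps each atom to the integer class used in the atom-type label map:
#' 1 = C-alpha, 2 = C-beta, 3 = backbone carbonyl carbon, 4 = oxygen,
#' 5 = nitrogen, 0 = everything else (other carbons, sulfur, phosphorus,
#' metals). Classes 1-3 require a standard amino-acid residue in a non-HETATM
#' record, which keeps e.g. calcium ions (atom name "CA" in hetero records)
#' out of the C-alpha class. Oxygen/nitrogen classes apply to any residue
#' type, so nucleic-acid O/N atoms are labeled too. Precedence is the listed
#' order.
#'
#' @param structure an atom tibble ([read_assembly()] schema) or a data frame
#'   with at least `name`, `element`, `res_name`, `is_hetero`.
#' @return Integer vector of class codes in 0..5, one per atom.
#' @examples
#' classify_atoms(data.frame(name = "CA", element = "C", res_name = "ALA",
#'                           is_hetero = FALSE)) # 1
#' @export
classify_atoms <- function(structure) {
  name <- structure$name
  element <- toupper(structure$element)
  aa <- structure$res_name %in% .standard_aa & !structure$is_hetero
  code <- integer(nrow(structure))
  code[element == "N"] <- 5L
  code[element == "O"] <- 4L
  code[aa & name == "C"] <- 3L
  code[aa & name == "CB"] <- 2L
  code[aa & name == "CA"] <- 1L
  code
}
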