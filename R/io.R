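# Configuration readers/writers: GRO (nm, fixed columns), PDB (Angstrom,
# ATOM/HETATM + CRYST1), extended XYZ (Angstrom, Lattice= comment line).
#
# Role assignment is by residue/molecule name: names in `water_residues`
# become water (oxygen/hydrogen split by element), everything else polymer.
# The coordinate formats carry no masses, so atoms are re-massed from the
# element table on read; coarse-grained bead masses survive only through the
# `mass_overrides` argument.

DEFAULT_WATER_RESIDUES <- c("SOL", "HOH", "WAT", "TIP3", "SPC")

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  two <- substr(nm, 1, 2)
  two <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
  ifelse(two %in% names(ATOMIC_MASSES), two, substr(nm, 1, 1))
}

assign_roles <- function(resname, element, water_residues) {
  is_water <- toupper(resname) %in% toupper(water_residues)
  role <- rep("polymer", length(resname))
  role[is_water & element == "O"] <- "water_O"
  role[is_water & element == "H"] <- "water_H"
  if (any(is_water & !element %in% c("O", "H"))) {
    stop("water residue contains atoms that are neither O nor H; ",
         "adjust water_residues or fix the input")
  }
  role
}

build_config_from_records <- function(xyz, resname, atomname, molecule_id,
                                      box, water_residues, mass_overrides,
                                      frame_index, validate) {
  element <- guess_element(atomname)
  role <- assign_roles(resname, element, water_residues)
  mass <- atomic_mass(element)
  if (length(mass_overrides)) {
    hit <- match(atomname, names(mass_overrides))
    mass[!is.na(hit)] <- mass_overrides[hit[!is.na(hit)]]
  }
  atoms <- atom_table(xyz, role, element, molecule_id, mass = mass)
  configuration(atoms, box, frame_index = frame_index, validate = validate)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb", "xyz")) return(ext)
  stop("cannot infer format from extension '", ext,
       "'; pass format = \"gro\"/\"pdb\"/\"xyz\"")
}

#' Read molecular configurations from GRO, PDB or extended-XYZ files
#'
#' Positions are converted to nm internally (GRO is already nm; PDB and XYZ
#' are Angstrom). Multi-frame files (concatenated GRO/XYZ frames, PDB MODEL
#' records) yield one configuration per frame.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param water_residues Residue names mapped to water; all other residues
#'   are polymer.
#' @param mass_overrides Named numeric vector of per-atom-name masses (g/mol)
#'   overriding the element table (used for coarse-grained beads).
#' @param validate Check water composition (default TRUE).
#' @return A list of [configuration()] objects, one per frame.
#' @export
read_configurations <- function(path, format = "auto",
                                water_residues = DEFAULT_WATER_RESIDUES,
                                mass_overrides = numeric(),
                                validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format, c("auto", "gro", "pdb", "xyz"))
  if (format == "auto") format <- detect_format(path)
  switch(format,
         gro = read_gro(path, water_residues, mass_overrides, validate),
         pdb = read_pdb_frames(path, water_residues, mass_overrides, validate),
         xyz = read_xyz(path, water_residues, mass_overrides, validate))
}

#' Read a single-frame configuration
#'
#' As [read_configurations()] but returns the first frame (with a warning if
#' the file holds more than one).
#'
#' @inheritParams read_configurations
#' @return A [configuration()].
#' @export
read_configuration <- function(path, format = "auto",
                               water_residues = DEFAULT_WATER_RESIDUES,
                               mass_overrides = numeric(),
                               validate = TRUE) {
  frames <- read_configurations(path, format, water_residues, mass_overrides,
                                validate)
  if (length(frames) > 1) {
    warning("file contains ", length(frames),
            " frames; returning the first")
  }
  frames[[1]]
}

read_gro <- function(path, water_residues, mass_overrides, validate) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; fidx <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO atom-count line at line ", i + 1L,
                            " of ", path)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    boxline <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    if (length(boxline) < 3) stop("malformed GRO box line in ", path)
    if (length(boxline) > 3 && any(as.numeric(boxline[4:length(boxline)]) != 0)) {
      stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
    }
    box <- new_box(as.numeric(boxline[1:3]))
    resid <- as.integer(substr(at, 1, 5))
    resname <- trimws(substr(at, 6, 10))
    atomname <- trimws(substr(at, 11, 15))
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    frames[[fidx]] <- build_config_from_records(
      xyz, resname, atomname, resid, box, water_residues, mass_overrides,
      fidx, validate)
    fidx <- fidx + 1L
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

parse_cryst1 <- function(path) {
  lines <- readLines(path, n = 500L)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("PDB file ", path, " has no CRYST1 record; ",
                        "a periodic box is required")
  a <- as.numeric(substr(cl[1], 7, 15))
  b <- as.numeric(substr(cl[1], 16, 24))
  c_ <- as.numeric(substr(cl[1], 25, 33))
  angles <- c(as.numeric(substr(cl[1], 34, 40)),
              as.numeric(substr(cl[1], 41, 47)),
              as.numeric(substr(cl[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3)) {
    stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
  }
  new_box(c(a, b, c_) / 10)  # Angstrom -> nm
}

read_pdb_frames <- function(path, water_residues, mass_overrides, validate) {
  box <- parse_cryst1(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atomname <- pdb$atom$elety
  resname <- pdb$atom$resid
  molid <- pdb$atom$resno
  nframes <- nrow(pdb$xyz)
  lapply(seq_len(nframes), function(f) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    build_config_from_records(xyz, resname, atomname, molid, box,
                              water_residues, mass_overrides, f, validate)
  })
}

read_xyz <- function(path, water_residues, mass_overrides, validate) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; fidx <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) stop("malformed XYZ count line at line ", i, " of ", path)
    comment <- lines[i + 1L]
    mlat <- regmatches(comment,
                       regexpr('Lattice="[^"]+"', comment))
    if (!length(mlat)) stop("XYZ frame lacks a Lattice=\"...\" box spec in ",
                            path)
    lat <- as.numeric(strsplit(gsub('Lattice="|"', "", mlat), "\\s+")[[1]])
    if (length(lat) != 9) stop("Lattice spec must have 9 numbers in ", path)
    off <- lat[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off) > 1e-8)) {
      stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
    }
    box <- new_box(lat[c(1, 5, 9)] / 10)  # Angstrom -> nm
    at <- lines[(i + 2L):(i + 1L + natoms)]
    tok <- strsplit(trimws(at), "\\s+")
    name <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3))) / 10
    # extended-XYZ has no residue field: species column may carry name:resname
    has_res <- grepl(":", name, fixed = TRUE)
    resname <- ifelse(has_res, sub("^[^:]+:", "", name), "UNK")
    atomname <- sub(":.*$", "", name)
    molid <- vapply(tok, function(t)
      if (length(t) >= 5) as.integer(t[5]) else NA_integer_, 1L)
    if (anyNA(molid)) molid <- seq_len(natoms)
    frames[[fidx]] <- build_config_from_records(
      xyz, resname, atomname, molid, box, water_residues, mass_overrides,
      fidx, validate)
    fidx <- fidx + 1L
    i <- i + 2L + natoms
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

config_record_fields <- function(config) {
  a <- config$atoms
  resname <- ifelse(a$role == "polymer", "POL", "SOL")
  atomname <- ifelse(a$role == "water_O", "OW",
                     ifelse(a$role == "water_H", "HW", a$element))
  list(resname = resname, atomname = atomname)
}

#' Write a configuration to GRO, PDB or extended-XYZ
#'
#' Water molecules are written with residue name SOL (atom names OW/HW),
#' polymer atoms with residue name POL; [read_configurations()] maps these
#' back by default. Masses are not representable in these formats.
#'
#' @param config A [configuration()].
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param append Append as an additional frame (GRO/XYZ only).
#' @return `path`, invisibly.
#' @export
write_configuration <- function(config, path, format = "auto",
                                append = FALSE) {
  format <- match.arg(format, c("auto", "gro", "pdb", "xyz"))
  if (format == "auto") format <- detect_format(path)
  a <- config$atoms
  rec <- config_record_fields(config)
  L <- config$box$lengths
  if (format == "gro") {
    lines <- c("generated by hydrolayers", sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$molecule_id %% 100000L, rec$resname, rec$atomname,
                       seq_len(nrow(a)) %% 100000L, a$x, a$y, a$z),
               sprintf("%10.5f%10.5f%10.5f", L[1], L[2], L[3]))
  } else if (format == "pdb") {
    if (append) stop("multi-frame PDB writing is not supported; use GRO/XYZ")
    lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       L[1] * 10, L[2] * 10, L[3] * 10, 90, 90, 90),
               sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(a)) %% 100000L, substr(rec$atomname, 1, 4),
                       substr(rec$resname, 1, 3), a$molecule_id %% 10000L,
                       a$x * 10, a$y * 10, a$z * 10, substr(a$element, 1, 2)),
               "END")
  } else {
    lat <- sprintf('Lattice="%.5f 0 0 0 %.5f 0 0 0 %.5f" Properties=species:S:1:pos:R:3',
                   L[1] * 10, L[2] * 10, L[3] * 10)
    lines <- c(sprintf("%d", nrow(a)), lat,
               sprintf("%s %12.5f %12.5f %12.5f %d",
                       paste0(rec$atomname, ":", rec$resname),
                       a$x * 10, a$y * 10, a$z * 10, a$molecule_id))
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
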