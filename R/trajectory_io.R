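#' Read per-frame water coordinates from a multi-model PDB file
#'
#' The trajectory dialect is a MODEL/ENDMDL-delimited multi-model PDB in
#' which each model is one solvent snapshot. Waters are identified by
#' residue name against a configurable whitelist (case-insensitive);
#' all other records are ignored. Each water must contribute exactly one
#' oxygen and two hydrogens. A file without MODEL records is read as a
#' single frame. A `CRYST1` record, when present, supplies periodic box
#' lengths for minimum-image distance handling.
#'
#' Models may differ in atom count (e.g. transiently absent waters), which
#' is why each model is parsed independently.
#'
#' @param path Path to the PDB file.
#' @param format Input dialect; only `"pdb"` (multi-model PDB) is built in.
#' @param water_resnames Residue names treated as water
#'   (default `HOH`, `SOL`, `WAT`, `TIP3`).
#' @return A [water_trajectory()]: one [water_frame()] per model, in file
#'   order, with `frame_index` equal to the MODEL serial (or 1).
#' @export
read_water_frames <- function(path, format = c("pdb", "gro"),
                              water_resnames = c("HOH", "SOL", "WAT",
                                                 "TIP3")) {
  format <- match.arg(format)
  if (format != "pdb")
    stop("only the multi-model PDB dialect is built in; convert GRO/XTC ",
         "trajectories to multi-model PDB first", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_records(lines, path)
  rec <- substr(lines, 1L, 6L)
  model_starts <- which(rec == "MODEL ")
  box <- .parse_cryst1(lines)
  if (length(model_starts) == 0L) {
    chunks <- list(lines)
    model_ids <- 1L
  } else {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    chunks <- Map(function(s, e) lines[s:e], model_starts, model_ends)
    model_ids <- suppressWarnings(
      as.integer(substr(lines[model_starts], 7L, 14L)))
    if (anyNA(model_ids)) model_ids <- seq_along(model_starts)
  }
  frames <- vector("list", length(chunks))
  for (m in seq_along(chunks)) {
    frames[[m]] <- .parse_model_waters(chunks[[m]], model_ids[m],
                                       toupper(water_resnames), box, path)
  }
  if (length(frames) == 0L)
    stop("no frames found in ", path, call. = FALSE)
  water_trajectory(frames)
}

# cheap structural validation so malformed records fail with a line number
.validate_pdb_records <- function(lines, path) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  if (!length(idx)) return(invisible())
  bad_len <- idx[nchar(lines[idx]) < 54L]
  if (length(bad_len))
    stop("malformed PDB record (short line) at line ", bad_len[1],
         " of ", path, call. = FALSE)
  xyz <- suppressWarnings(cbind(
    as.numeric(substr(lines[idx], 31L, 38L)),
    as.numeric(substr(lines[idx], 39L, 46L)),
    as.numeric(substr(lines[idx], 47L, 54L))))
  bad <- idx[rowSums(is.na(xyz)) > 0L]
  if (length(bad))
    stop("malformed PDB record (unparseable coordinates) at line ",
         bad[1], " of ", path, call. = FALSE)
  invisible()
}

.parse_cryst1 <- function(lines) {
  cr <- lines[startsWith(lines, "CRYST1")]
  if (!length(cr)) return(NULL)
  box <- suppressWarnings(as.numeric(c(substr(cr[1], 7L, 15L),
                                       substr(cr[1], 16L, 24L),
                                       substr(cr[1], 25L, 33L))))
  if (anyNA(box) || any(box <= 0)) return(NULL)
  box
}

# parse one model chunk through bio3d and assemble a water_frame
.parse_model_waters <- function(chunk, frame_index, whitelist, box, path) {
  atom_lines <- chunk[startsWith(chunk, "ATOM") |
                        startsWith(chunk, "HETATM")]
  if (!length(atom_lines))
    return(water_frame(NULL, NULL, NULL, frame_index = frame_index,
                       box = box))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(atom_lines, "END"), tmp)
  pdb <- tryCatch(bio3d::read.pdb(tmp, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse model ", frame_index, " of ",
                         path, ": ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- toupper(trimws(at$resid)) %in% whitelist
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    return(water_frame(NULL, NULL, NULL, frame_index = frame_index,
                       box = box))
  grp <- paste(at$chain, at$resno, at$insert, sep = "|")
  grp <- factor(grp, levels = unique(grp))
  split_idx <- split(seq_len(nrow(at)), grp)
  nw <- length(split_idx)
  o <- matrix(NA_real_, nw, 3L)
  h1 <- matrix(NA_real_, nw, 3L)
  h2 <- matrix(NA_real_, nw, 3L)
  for (w in seq_len(nw)) {
    rows <- split_idx[[w]]
    res <- at[rows, , drop = FALSE]
    elety <- toupper(trimws(res$elety))
    is_o <- startsWith(elety, "O")
    is_h <- startsWith(elety, "H") | grepl("^[0-9]H", elety)
    lab <- sprintf("water %s %s%s (frame %d)", trimws(res$resid[1]),
                   res$chain[1], res$resno[1], frame_index)
    if (sum(is_o) != 1L)
      stop(lab, " must have exactly 1 oxygen, found ", sum(is_o),
           call. = FALSE)
    if (sum(is_h) != 2L)
      stop(lab, " must have exactly 2 hydrogens, found ", sum(is_h),
           call. = FALSE)
    o[w, ] <- unlist(res[is_o, c("x", "y", "z")])
    hh <- res[is_h, c("x", "y", "z"), drop = FALSE]
    h1[w, ] <- unlist(hh[1, ]); h2[w, ] <- unlist(hh[2, ])
  }
  water_frame(o, h1, h2, frame_index = frame_index, box = box)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with waters as `HOH` residues
#' (atoms `O`, `H1`, `H2`), plus a `CRYST1` record when the first frame
#' carries box lengths. The output round-trips through
#' [read_water_frames()] to PDB coordinate precision (1e-3 Angstrom).
#'
#' @param frames A [water_trajectory()] or list of [water_frame()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_water_frames <- function(frames, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  first_box <- frames[[1]]$box
  if (!is.null(first_box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      first_box[1], first_box[2], first_box[3]), con)
  for (f in frames) {
    writeLines(sprintf("MODEL %8d", f$frame_index), con)
    nw <- n_waters(f)
    if (nw > 0L) {
      serial <- 0L
      recs <- character(3L * nw)
      for (w in seq_len(nw)) {
        xyz <- rbind(f$o[w, ], f$h1[w, ], f$h2[w, ])
        nm <- c("O", "H1", "H2"); el <- c("O", "H", "H")
        for (a in 1:3) {
          serial <- serial + 1L
          recs[serial] <- sprintf(
            "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial %% 100000L, nm[a], "HOH", "A", w %% 10000L,
            xyz[a, 1L], xyz[a, 2L], xyz[a, 3L], el[a])
        }
      }
      writeLines(recs, con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a binding-site definition from a YAML or JSON config
#'
#' A binding site is an ordered list of residues, each contributing its
#' four backbone atoms N, C-alpha, C, O in that fixed order. Side chains
#' are deliberately excluded so that non-identical residues matched by a
#' pocket alignment (e.g. the KLIFS kinase numbering) remain comparable.
#' Because the protein is positionally restrained during the solvent
#' production run, one static coordinate set per protein suffices.
#'
#' The config schema (YAML shown; JSON is isomorphic):
#' ```
#' protein_label: CDK2
#' reference_pdb: cdk2_ref.pdb      # optional; resolved relative to config
#' residues:
#'   - {chain: A, resnum: 10, resname: GLY}            # from reference_pdb
#'   - chain: A
#'     resnum: 11
#'     resname: GLU
#'     atoms: {N: [x,y,z], CA: [x,y,z], C: [x,y,z], O: [x,y,z]}  # inline
#' ```
#' Residues with an `atoms` block use the inline coordinates; the rest are
#' pulled from `reference_pdb`. Every residue must yield all four backbone
#' atoms.
#'
#' @param path Path to the YAML (`.yml`/`.yaml`) or JSON config.
#' @param expected_residues Optional residue count to enforce.
#' @return A [binding_site()] object.
#' @export
read_binding_site <- function(path, expected_residues = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else stop("unsupported config extension: .", ext, call. = FALSE)
  if (is.null(cfg$protein_label) || is.null(cfg$residues))
    stop("binding-site config needs 'protein_label' and 'residues'",
         call. = FALSE)
  residues <- cfg$residues
  nres <- length(residues)
  if (!is.null(expected_residues) && nres != expected_residues)
    stop("binding-site config lists ", nres, " residues, expected ",
         expected_residues, call. = FALSE)
  ref <- NULL
  if (!is.null(cfg$reference_pdb)) {
    ref_path <- cfg$reference_pdb
    if (!file.exists(ref_path))
      ref_path <- file.path(dirname(path), cfg$reference_pdb)
    if (!file.exists(ref_path))
      stop("reference_pdb not found: ", cfg$reference_pdb, call. = FALSE)
    ref <- bio3d::read.pdb(ref_path, verbose = FALSE)$atom
  }
  bb <- c("N", "CA", "C", "O")
  coords <- matrix(NA_real_, nres * 4L, 3L)
  info <- data.frame(chain = character(nres), resnum = integer(nres),
                     resname = character(nres))
  for (r in seq_len(nres)) {
    res <- residues[[r]]
    lab <- sprintf("residue %s%s (%s)", res$chain, res$resnum, res$resname)
    info$chain[r] <- as.character(res$chain)
    info$resnum[r] <- as.integer(res$resnum)
    info$resname[r] <- as.character(res$resname)
    if (!is.null(res$atoms)) {
      # YAML 1.1 parses a bare N key as boolean false; accept it as "N"
      names(res$atoms)[names(res$atoms) == "FALSE"] <- "N"
      for (a in seq_along(bb)) {
        xyz <- res$atoms[[bb[a]]]
        if (is.null(xyz) || length(unlist(xyz)) != 3L)
          stop(lab, " lacks inline coordinates for backbone atom ", bb[a],
               call. = FALSE)
        coords[(r - 1L) * 4L + a, ] <- as.numeric(unlist(xyz))
      }
    } else {
      if (is.null(ref))
        stop(lab, " has no inline atoms and no reference_pdb was given",
             call. = FALSE)
      sel <- ref$chain == res$chain & ref$resno == res$resnum
      for (a in seq_along(bb)) {
        hit <- which(sel & toupper(trimws(ref$elety)) == bb[a])
        if (length(hit) != 1L)
          stop(lab, " lacks backbone atom ", bb[a], " in reference PDB",
               call. = FALSE)
        coords[(r - 1L) * 4L + a, ] <-
          unlist(ref[hit, c("x", "y", "z")])
      }
    }
  }
  binding_site(cfg$protein_label, info, coords)
}

#' Construct a binding site
#'
#' @param protein_label Text label for the protein.
#' @param residues Data frame with columns `chain`, `resnum`, `resname`,
#'   one row per binding-site residue in pocket-alignment order.
#' @param coords Numeric matrix of backbone coordinates, `4 * nrow(residues)`
#'   rows by 3 columns, residue-major with atoms in the fixed order
#'   N, CA, C, O.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(protein_label, residues, coords) {
  coords <- .as_coord_matrix(coords)
  stopifnot(is.data.frame(residues),
            all(c("chain", "resnum", "resname") %in% names(residues)),
            nrow(coords) == 4L * nrow(residues))
  labels <- as.vector(t(outer(
    paste0(residues$resname, residues$resnum),
    c("N", "CA", "C", "O"), paste, sep = ".")))
  rownames(coords) <- labels
  structure(list(protein_label = as.character(protein_label),
                 residues = residues, coords = coords),
            class = "binding_site")
}

#' Number of binding-site atoms (4 per residue)
#' @param site A [binding_site()].
#' @return Integer atom count.
#' @export
n_site_atoms <- function(site) {
  stopifnot(inherits(site, "binding_site"))
  nrow(site$coords)
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("binding_site '%s': %d residues, %d backbone atoms\n",
              x$protein_label, nrow(x$residues), n_site_atoms(x)))
  invisible(x)
}

#' Pair two binding sites by aligned residue position
#'
#' Residue k of the reference corresponds to residue k of the query (a
#' KLIFS-style positional correspondence); both sites must therefore list
#' the same number of residues.
#'
#' @param reference_site,query_site [binding_site()] objects.
#' @return An object of class `site_pairing`.
#' @export
site_pairing <- function(reference_site, query_site) {
  stopifnot(inherits(reference_site, "binding_site"),
            inherits(query_site, "binding_site"))
  nr <- nrow(reference_site$residues); nq <- nrow(query_site$residues)
  if (nr != nq)
    stop("paired binding sites must have equal residue counts (",
         nr, " vs ", nq, ")", call. = FALSE)
  structure(list(reference_site = reference_site, query_site = query_site,
                 pairing = seq_len(nr)),
            class = "site_pairing")
}

#' Write detected rings to a TSV table
#'
#' Columns: `frame_index`, `water_i`, `water_j`, `water_k`, `e_ij`,
#' `e_jk`, `e_ik` (kcal/mol), `centroid_x`/`_y`/`_z` (Angstrom); one row
#' per ring, water triple ascending. Full double precision is retained so
#' the table round-trips through [read_rings()].
#'
#' @param rings A `twn_rings` data frame from [detect_twns()] or
#'   [detect_twns_trajectory()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rings <- function(rings, path) {
  stopifnot(is.data.frame(rings))
  cols <- c("frame_index", "water_i", "water_j", "water_k",
            "e_ij", "e_jk", "e_ik", "centroid_x", "centroid_y",
            "centroid_z")
  stopifnot(all(cols %in% names(rings)))
  df <- rings[, cols, drop = FALSE]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ring TSV written by [write_rings()]
#' @param path Path to the TSV.
#' @return A `twn_rings` data frame.
#' @export
read_rings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  cols <- c("frame_index", "water_i", "water_j", "water_k",
            "e_ij", "e_jk", "e_ik", "centroid_x", "centroid_y",
            "centroid_z")
  if (!all(cols %in% names(df)))
    stop("not a ring table: missing columns ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  class(df) <- c("twn_rings", "data.frame")
  df
}
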