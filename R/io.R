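#' Construct a ProteinModel
#'
#' @param modelId model identifier.
#' @param sequence one-letter sequence (length L string).
#' @param resno integer residue numbers (length L, strictly increasing);
#'   defaults to 1:L.
#' @param atoms data.frame with columns resno, elety, x, y, z.
#' @return a validated \linkS4class{ProteinModel}.
#' @export
proteinModel <- function(modelId, sequence, atoms,
                         resno = seq_len(nchar(sequence))) {
  new("ProteinModel", modelId = as.character(modelId),
      sequence = toupper(sequence),
      resno = as.integer(resno),
      atoms = as.data.frame(atoms)[, c("resno", "elety", "x", "y", "z")])
}

#' Construct a ModelPool
#'
#' @param targetId target identifier.
#' @param models list of \linkS4class{ProteinModel}; names are taken from
#'   the model ids.
#' @param native optional native \linkS4class{ProteinModel}.
#' @param externalScores optional data.frame from \code{readScoreTable()}.
#' @param ssPred,saPred optional predicted 3-state / 2-state strings.
#' @return a validated \linkS4class{ModelPool}.
#' @export
modelPool <- function(targetId, models, native = NULL,
                      externalScores = NULL,
                      ssPred = NA_character_, saPred = NA_character_) {
  names(models) <- vapply(models, modelId, character(1))
  new("ModelPool", targetId = as.character(targetId), models = models,
      native = native, externalScores = externalScores,
      ssPred = ssPred, saPred = saPred)
}

#' Read a protein model from a PDB file
#'
#' Reads ATOM records of the first chain of the first MODEL block (the
#' usual convention for single-domain decoys). Alternate locations are
#' resolved to the highest-occupancy altloc. The sequence is derived from
#' residue names; unknown residues become "X". Every residue must carry a
#' CA atom.
#'
#' @param path PDB file path.
#' @param modelId id to assign; defaults to the file name without
#'   extension.
#' @return a \linkS4class{ProteinModel}.
#' @export
readPdb <- function(path, modelId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[at$chain %in% at$chain[1] | (is.na(at$chain) & is.na(at$chain[1])),
           , drop = FALSE]
  # altloc: keep highest occupancy per (residue, atom name)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    i[which.max(occ[i])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]

  resno <- unique(at$resno)
  resid3 <- at$resid[match(resno, at$resno)]
  aa <- unname(AA3TO1[toupper(resid3)])
  aa[is.na(aa)] <- "X"

  ca <- resno %in% at$resno[at$elety == "CA"]
  if (!all(ca))
    stop("residue(s) without CA atom in ", path, ": ",
         paste(resno[!ca], collapse = ", "))

  proteinModel(modelId, paste(aa, collapse = ""),
               atoms = data.frame(resno = at$resno, elety = at$elety,
                                  x = at$x, y = at$y, z = at$z,
                                  stringsAsFactors = FALSE),
               resno = resno)
}

#' Write a protein model to a PDB file
#'
#' Emits standard ATOM records (8.3 coordinate fields) followed by END;
#' \code{readPdb(writePdb(m))} reproduces coordinates to the printed
#' precision.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePdb <- function(model, path) {
  stopifnot(is(model, "ProteinModel"))
  at <- model@atoms
  seqv <- strsplit(model@sequence, "")[[1]]
  resid3 <- unname(AA1TO3[seqv[match(at$resno, model@resno)]])
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resno, resid = resid3,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = "A", o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with exactly one record.
#' @return uppercase sequence string without whitespace.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    stop("expected exactly one FASTA record in ", path,
         ", found ", length(set))
  toupper(gsub("\\s", "", as.character(set[[1]])))
}

#' Read a per-model external score table
#'
#' Tab-delimited with a header: a \code{model} id column plus raw score
#' columns (recognised names: dfire2, rwplus, rf_cb_srs_od, dope, goap,
#' opus, proq2, modelevaluator, qprob; case-insensitive). Empty cells are
#' recorded as NA and imputed later during feature assembly, never here.
#'
#' @param path TSV file path.
#' @return data.frame with character \code{model} column and numeric
#'   score columns (NA = missing).
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"model" %in% names(tab))
    stop("score table must have a 'model' column: ", path)
  if (anyDuplicated(tab$model))
    stop("duplicate model ids in score table: ",
         paste(unique(tab$model[duplicated(tab$model)]), collapse = ", "))
  for (cn in setdiff(names(tab), "model")) {
    v <- trimws(tab[[cn]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad))
      stop("non-numeric value in column '", cn, "' of ", path, ": ",
           paste(v[bad], collapse = ", "))
    tab[[cn]] <- num
  }
  tab
}

#' Read a one-line prediction string (secondary structure or accessibility)
#'
#' @param path plain text file whose first non-empty line is the string.
#' @param L optional expected length; mismatch is an error.
#' @param alphabet optional allowed characters.
#' @return the string.
#' @export
readPredString <- function(path, L = NULL, alphabet = NULL) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (!length(lines)) stop("no prediction string in ", path)
  s <- lines[1]
  if (!is.null(L) && nchar(s) != L)
    stop("prediction string length ", nchar(s), " != expected ", L,
         " in ", path)
  if (!is.null(alphabet)) {
    ch <- unique(strsplit(s, "")[[1]])
    if (!all(ch %in% alphabet))
      stop("unexpected characters in ", path, ": ",
           paste(setdiff(ch, alphabet), collapse = ""))
  }
  s
}

#' Reduce an 8-state DSSP string to 3 states
#'
#' Convention: H,G,I -> H; E,B -> E; everything else -> C.
#'
#' @param ss8 8-state string (spaces allowed for coil).
#' @return 3-state string over {H,E,C}.
#' @export
reduceDssp <- function(ss8) {
  ch <- strsplit(ss8, "")[[1]]
  out <- rep("C", length(ch))
  out[ch %in% c("H", "G", "I")] <- "H"
  out[ch %in% c("E", "B")] <- "E"
  paste(out, collapse = "")
}
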