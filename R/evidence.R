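#' Assemble an evidence set
#'
#' Bundles and validates all observed evidence for the hierarchical model:
#' Y2H replicate records, pull-down complex records, literature report
#' indicators, and the homology map linking human proteins to orthologs in
#' other organisms. Identifiers are opaque strings; every protein referenced
#' by a record must belong to the universe (which is derived from the
#' records when not supplied).
#'
#' Pairs are stored in canonical order (`protein_a < protein_b`). Records on
#' self-pairs (`i == j`) carry no information under the model and are
#' dropped with a warning.
#'
#' @param y2h data frame with columns `protein_a`, `protein_b`, `source_id`,
#'   `replicate`, `observed` (0/1) and optionally `organism` (default
#'   `"human"`). One row per replicate; replicate indices must be contiguous
#'   from 1 within each (pair, source).
#' @param complexes data frame with columns `bait`, `members`
#'   (comma-separated protein ids, bait excluded), `experiment_id` and
#'   optionally `organism`.
#' @param literature data frame with columns `protein_a`, `protein_b`,
#'   `channel` (`"H"` or `"L"`) and `observed` (0/1); human pairs only, at
#'   most one record per (pair, channel).
#' @param homology data frame with columns `human_protein`, `ortholog`,
#'   `organism`, `identity` (sequence identity in `[0, 1]`).
#' @param universe optional data frame with columns `protein`, `organism`
#'   fixing the protein universe (useful to retain proteins without
#'   evidence).
#'
#' @return An object of class `ppi_evidence`.
#' @export
#' @examples
#' ev <- ppi_evidence(
#'   y2h = data.frame(protein_a = "P1", protein_b = "P2",
#'                    source_id = "screen1", replicate = 1, observed = 1))
#' ev
ppi_evidence <- function(y2h = NULL, complexes = NULL, literature = NULL,
                         homology = NULL, universe = NULL) {
  empty_y2h <- data.frame(protein_a = character(), protein_b = character(),
                          source_id = character(), replicate = integer(),
                          observed = integer(), organism = character(),
                          stringsAsFactors = FALSE)
  empty_cplx <- data.frame(bait = character(), members = character(),
                           experiment_id = character(), organism = character(),
                           stringsAsFactors = FALSE)
  empty_lit <- data.frame(protein_a = character(), protein_b = character(),
                          channel = character(), observed = integer(),
                          stringsAsFactors = FALSE)
  empty_hom <- data.frame(human_protein = character(), ortholog = character(),
                          organism = character(), identity = numeric(),
                          stringsAsFactors = FALSE)

  y2h <- if (is.null(y2h) || !nrow(y2h)) empty_y2h else {
    y2h <- as.data.frame(y2h, stringsAsFactors = FALSE)
    if (is.null(y2h$organism)) y2h$organism <- "human"
    stopifnot(all(c("protein_a", "protein_b", "source_id", "replicate",
                    "observed") %in% names(y2h)))
    y2h
  }
  complexes <- if (is.null(complexes) || !nrow(complexes)) empty_cplx else {
    complexes <- as.data.frame(complexes, stringsAsFactors = FALSE)
    if (is.null(complexes$organism)) complexes$organism <- "human"
    stopifnot(all(c("bait", "members", "experiment_id") %in% names(complexes)))
    complexes
  }
  literature <- if (is.null(literature) || !nrow(literature)) empty_lit else {
    literature <- as.data.frame(literature, stringsAsFactors = FALSE)
    stopifnot(all(c("protein_a", "protein_b", "channel", "observed") %in%
                    names(literature)))
    if (!all(literature$channel %in% c("H", "L")))
      stop("literature channel must be 'H' or 'L'")
    literature
  }
  homology <- if (is.null(homology) || !nrow(homology)) empty_hom else {
    homology <- as.data.frame(homology, stringsAsFactors = FALSE)
    stopifnot(all(c("human_protein", "ortholog", "organism", "identity") %in%
                    names(homology)))
    if (any(homology$identity < 0 | homology$identity > 1))
      stop("sequence identities must lie in [0, 1]")
    homology
  }

  # drop self-pairs
  for (nm in c("y2h", "literature")) {
    d <- get(nm)
    self <- d$protein_a == d$protein_b
    if (any(self)) {
      warning(sum(self), " self-pair record(s) dropped from ", nm)
      assign(nm, d[!self, , drop = FALSE])
    }
  }
  # canonical pair order
  canon <- function(d) {
    sw <- d$protein_a > d$protein_b
    if (any(sw)) {
      tmp <- d$protein_a[sw]
      d$protein_a[sw] <- d$protein_b[sw]
      d$protein_b[sw] <- tmp
    }
    d
  }
  y2h <- canon(y2h)
  literature <- canon(literature)

  if (nrow(y2h)) {
    key <- paste(y2h$protein_a, y2h$protein_b, y2h$source_id, sep = "\r")
    ok <- vapply(split(y2h$replicate, key),
                 function(r) identical(sort(as.integer(r)),
                                       seq_along(r)), logical(1))
    if (!all(ok))
      stop("Y2H replicate indices must be contiguous from 1 within each ",
           "(pair, source)")
  }
  if (nrow(literature)) {
    key <- paste(literature$protein_a, literature$protein_b,
                 literature$channel, sep = "\r")
    if (anyDuplicated(key))
      stop("at most one literature record per (pair, channel)")
  }
  if (nrow(complexes)) {
    mem <- strsplit(complexes$members, ",", fixed = TRUE)
    hasbait <- mapply(function(b, m) b %in% m, complexes$bait, mem)
    if (any(hasbait)) {
      warning("bait removed from its own member list in ",
              sum(hasbait), " complex record(s)")
      complexes$members <- vapply(seq_along(mem), function(k)
        paste(setdiff(mem[[k]], complexes$bait[k]), collapse = ","),
        character(1))
    }
  }

  # universe: supplied or derived from the records
  org_of <- c()
  add <- function(prot, org) {
    if (!length(prot)) return(invisible())
    new <- stats::setNames(org, prot)
    both <- intersect(names(org_of), prot)
    if (length(both) && any(org_of[both] != new[both]))
      stop("protein(s) assigned to two organisms: ",
           paste(both[org_of[both] != new[both]], collapse = ", "))
    org_of <<- c(org_of, new[setdiff(prot, names(org_of))])
  }
  add(y2h$protein_a, y2h$organism); add(y2h$protein_b, y2h$organism)
  add(complexes$bait, complexes$organism)
  if (nrow(complexes)) {
    mem <- strsplit(complexes$members, ",", fixed = TRUE)
    for (k in seq_along(mem)) add(mem[[k]],
                                  rep(complexes$organism[k], length(mem[[k]])))
  }
  add(literature$protein_a, rep("human", nrow(literature)))
  add(literature$protein_b, rep("human", nrow(literature)))
  add(homology$human_protein, rep("human", nrow(homology)))
  add(homology$ortholog, homology$organism)

  if (is.null(universe)) {
    universe <- data.frame(protein = names(org_of),
                           organism = unname(org_of),
                           stringsAsFactors = FALSE)
    universe <- universe[order(universe$organism != "human",
                               universe$organism, universe$protein), ]
    rownames(universe) <- NULL
  } else {
    universe <- as.data.frame(universe, stringsAsFactors = FALSE)
    stopifnot(all(c("protein", "organism") %in% names(universe)))
    if (anyDuplicated(universe$protein))
      stop("universe protein identifiers must be unique")
    missing <- setdiff(names(org_of), universe$protein)
    if (length(missing))
      stop("evidence references protein(s) absent from the universe: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...")
  }

  structure(list(universe = universe, y2h = y2h, complexes = complexes,
                 literature = literature, homology = homology),
            class = "ppi_evidence")
}

#' @export
print.ppi_evidence <- function(x, ...) {
  orgs <- table(x$universe$organism)
  cat("PPI evidence set\n")
  cat("  proteins: ", nrow(x$universe), " (",
      paste(names(orgs), orgs, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  Y2H replicate records: ", nrow(x$y2h), "\n", sep = "")
  cat("  complex records:       ", nrow(x$complexes), "\n", sep = "")
  cat("  literature records:    ", nrow(x$literature), "\n", sep = "")
  cat("  homolog mappings:      ", nrow(x$homology), "\n", sep = "")
  invisible(x)
}

# organisms in a fixed order: human first, then the others alphabetically
evidence_organisms <- function(ev) {
  others <- sort(setdiff(unique(ev$universe$organism), "human"))
  c("human", others)
}

# proteins of one organism, in universe order
organism_proteins <- function(ev, organism) {
  ev$universe$protein[ev$universe$organism == organism]
}

parse_members <- function(members) {
  lapply(strsplit(members, ",", fixed = TRUE),
         function(m) m[nzchar(m)])
}

#' Write / read an evidence set as TSV files
#'
#' Serializes the evidence set to plain tab-separated files in `dir`:
#' `y2h.tsv`, `complexes.tsv`, `literature.tsv` (same five-column schema as
#' Y2H, with the channel in `source_id`), `homology.tsv` and `universe.tsv`.
#' `read_evidence()` restores the identical object.
#'
#' @param ev a [ppi_evidence()] object.
#' @param dir directory (created if needed).
#' @return `write_evidence()` returns `dir` invisibly; `read_evidence()`
#'   returns a `ppi_evidence` object.
#' @export
write_evidence <- function(ev, dir) {
  stopifnot(inherits(ev, "ppi_evidence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(ev$y2h, "y2h.tsv")
  wr(ev$complexes, "complexes.tsv")
  lit <- data.frame(protein_a = ev$literature$protein_a,
                    protein_b = ev$literature$protein_b,
                    source_id = ev$literature$channel,
                    replicate = rep(1L, nrow(ev$literature)),
                    observed = ev$literature$observed,
                    stringsAsFactors = FALSE)
  wr(lit, "literature.tsv")
  wr(ev$homology, "homology.tsv")
  wr(ev$universe, "universe.tsv")
  invisible(dir)
}

#' @rdname write_evidence
#' @export
read_evidence <- function(dir) {
  rd <- function(f, required = FALSE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing evidence file: ", p)
      return(NULL)
    }
    cf <- utils::count.fields(p, sep = "\t", quote = "", blank.lines.skip = FALSE)
    bad <- which(cf != cf[1])
    if (length(bad))
      stop("malformed TSV in ", p, ": line ", bad[1], " has ", cf[bad[1]],
           " field(s), expected ", cf[1])
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  y2h <- rd("y2h.tsv")
  complexes <- rd("complexes.tsv")
  lit <- rd("literature.tsv")
  if (!is.null(lit) && nrow(lit)) {
    lit <- data.frame(protein_a = as.character(lit$protein_a),
                      protein_b = as.character(lit$protein_b),
                      channel = as.character(lit$source_id),
                      observed = lit$observed, stringsAsFactors = FALSE)
  } else lit <- NULL
  hom <- rd("homology.tsv")
  uni <- rd("universe.tsv")
  fix_chr <- function(d, cols) {
    if (is.null(d) || !nrow(d)) return(d)
    for (cl in intersect(cols, names(d))) d[[cl]] <- as.character(d[[cl]])
    d
  }
  ppi_evidence(
    y2h = fix_chr(y2h, c("protein_a", "protein_b", "source_id", "organism")),
    complexes = fix_chr(complexes, c("bait", "members", "experiment_id",
                                     "organism")),
    literature = lit,
    homology = fix_chr(hom, c("human_protein", "ortholog", "organism")),
    universe = fix_chr(uni, c("protein", "organism")))
}
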