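## Input/output: causal network, drug-target and DEG tables, subnetwork export.

#' Default effect mapping for causal-network edges
#'
#' Maps SIGNOR-style effect strings onto the binary effect used throughout the
#' package: strings containing \code{"up-regulates"} become \code{"UP"},
#' strings containing \code{"down-regulates"} become \code{"DOWN"}, and
#' everything else (complex formation, unknown, "modulation"-like relations)
#' is \code{"DISCARD"}ed, mirroring the manual binarisation applied to the
#' curated resource.
#'
#' @return A vectorised function from effect strings to
#'   \code{"UP"}/\code{"DOWN"}/\code{"DISCARD"}.
#' @examples
#' defaultEffectMapping()(c("up-regulates activity", "form complex"))
#' @export
defaultEffectMapping <- function() {
  function(x) {
    out <- rep("DISCARD", length(x))
    out[grepl("down-regulates", x, ignore.case = TRUE)] <- "DOWN"
    out[grepl("up-regulates", x, ignore.case = TRUE) &
        !grepl("down-regulates", x, ignore.case = TRUE)] <- "UP"
    out
  }
}

# Normalise a user-supplied mapping (function or named character vector)
# into a vectorised function returning UP/DOWN/DISCARD.
asMappingFun <- function(mapping) {
  if (is.function(mapping)) return(mapping)
  if (is.character(mapping) && !is.null(names(mapping))) {
    map <- mapping
    return(function(x) {
      out <- unname(map[x])
      out[is.na(out)] <- "DISCARD"
      out
    })
  }
  stop("mapping must be a function or a named character vector")
}

#' Parse a causal interaction network from a tab-separated file
#'
#' Reads a SIGNOR-style flat file (one row per directed causal relation) into
#' a [CausalNetwork-class]. Rows are dropped, with counts reported, when the
#' effect does not map onto up-/down-regulation, when the confidence score is
#' missing, non-numeric or outside (0, 1], or when the row is a self-loop
#' (a self-loop can never participate in a shortest path between distinct
#' genes). Column names are configurable because the flat-file header of the
#' upstream resource has changed across releases.
#'
#' @param path path to a tab-separated file with a header.
#' @param mapping effect mapping: a function from effect strings to
#'   \code{"UP"}/\code{"DOWN"}/\code{"DISCARD"}, or a named character vector;
#'   defaults to [defaultEffectMapping()].
#' @param columns named character vector locating the \code{source},
#'   \code{target}, \code{effect} and \code{score} columns in the file.
#' @param verbose emit per-category drop counts to stderr.
#' @return A [CausalNetwork-class]; \code{parseLog(net)} holds the counts of
#'   rows read, kept, and dropped by category, with
#'   \code{kept + dropped == read} asserted.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("ENTITYA\tENTITYB\tEFFECT\tSCORE",
#'              "A\tB\tup-regulates\t0.9",
#'              "B\tC\tdown-regulates activity\t0.4"), f)
#' net <- parseCausalNetwork(f)
#' edgeTable(net)
#' @export
parseCausalNetwork <- function(path,
    mapping = defaultEffectMapping(),
    columns = c(source = "ENTITYA", target = "ENTITYB",
                effect = "EFFECT", score = "SCORE"),
    verbose = TRUE) {
  fun <- asMappingFun(mapping)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing))
    stop("causal network file lacks required column(s): ",
         paste(missing, collapse = ", "))
  nRead <- nrow(raw)
  e <- data.frame(source = raw[[columns[["source"]]]],
                  target = raw[[columns[["target"]]]],
                  effectRaw = raw[[columns[["effect"]]]],
                  score = suppressWarnings(as.numeric(raw[[columns[["score"]]]])),
                  stringsAsFactors = FALSE)
  badScore <- is.na(e$score) | e$score <= 0 | e$score > 1
  e$effect <- fun(e$effectRaw)
  badEffect <- !badScore & e$effect == "DISCARD"
  selfLoop <- !badScore & !badEffect & e$source == e$target
  keep <- !(badScore | badEffect | selfLoop)
  log <- list(read = nRead, kept = sum(keep),
              dropped_bad_score = sum(badScore),
              dropped_unmappable_effect = sum(badEffect),
              dropped_self_loop = sum(selfLoop))
  stopifnot(log$kept + log$dropped_bad_score + log$dropped_unmappable_effect +
            log$dropped_self_loop == log$read)
  if (sum(badScore))
    warning(sum(badScore), " row(s) dropped: score missing or outside (0, 1]")
  if (verbose)
    logMsg("parse_causal_network",
           sprintf("read=%d kept=%d bad_score=%d unmappable_effect=%d self_loop=%d",
                   log$read, log$kept, log$dropped_bad_score,
                   log$dropped_unmappable_effect, log$dropped_self_loop))
  CausalNetwork(e[keep, c("source", "target", "effect", "score")],
                parseLog = log)
}

#' Write a causal network as a tab-separated edge table
#'
#' Writes the default parseable dialect (columns ENTITYA, ENTITYB, EFFECT,
#' SCORE, effects spelled \code{up-regulates}/\code{down-regulates}) so that
#' re-parsing yields an identical multiset of edges.
#'
#' @param net a [CausalNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCausalNetwork <- function(net, path) {
  e <- edgeTable(net)
  out <- data.frame(ENTITYA = e$source, ENTITYB = e$target,
                    EFFECT = ifelse(e$effect == "UP",
                                    "up-regulates", "down-regulates"),
                    SCORE = e$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default mode-of-action mapping for drug-target tables
#'
#' Binarises the free-text modes of action found in Therapeutic Target
#' Database-style files. Strings indicating activation (agonist, activator,
#' inducer, stimulator, up-regulation) map to \code{"UP"}; strings indicating
#' suppression (inhibitor, antagonist, blocker, suppressor, down-regulation)
#' map to \code{"DOWN"}; anything without a direct mapping (e.g. "Modulator")
#' is \code{"DISCARD"}ed.
#'
#' @return A vectorised mapping function.
#' @export
defaultMoaMapping <- function() {
  upPat <- "agonist|activat|induc|stimulat|up-?regulat|enhanc"
  downPat <- "antagonist|inhibit|block|suppress|down-?regulat"
  function(x) {
    out <- rep("DISCARD", length(x))
    isDown <- grepl(downPat, x, ignore.case = TRUE)
    isUp <- grepl(upPat, x, ignore.case = TRUE) & !isDown
    out[isDown] <- "DOWN"
    out[isUp] <- "UP"
    out
  }
}

#' Parse a drug-target table
#'
#' Reads a tab-separated drug-target file (one row per drug-target-MoA entry)
#' into a [DrugSet-class]. Entries whose mode of action does not map to
#' up-/down-regulation are dropped; drugs left with zero mapped targets are
#' excluded (both logged). Duplicate (drug, target) entries with different
#' modes of action are deliberately kept as distinct entries.
#'
#' @param path path to a tab-separated file with header.
#' @param moaMapping mode-of-action mapping (function or named character
#'   vector); defaults to [defaultMoaMapping()].
#' @param columns named character vector locating the \code{drug_id},
#'   \code{drug_name}, \code{target} and \code{moa} columns.
#' @param verbose emit counts to stderr.
#' @return A [DrugSet-class].
#' @export
parseDrugTargets <- function(path,
    moaMapping = defaultMoaMapping(),
    columns = c(drug_id = "DRUG_ID", drug_name = "DRUG_NAME",
                target = "TARGET", moa = "MOA"),
    verbose = TRUE) {
  fun <- asMappingFun(moaMapping)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing))
    stop("drug-target file lacks required column(s): ",
         paste(missing, collapse = ", "))
  t <- data.frame(drug_id = raw[[columns[["drug_id"]]]],
                  drug_name = raw[[columns[["drug_name"]]]],
                  target = raw[[columns[["target"]]]],
                  moa = fun(raw[[columns[["moa"]]]]),
                  stringsAsFactors = FALSE)
  nRead <- nrow(t)
  allDrugs <- unique(t$drug_id)
  keep <- t$moa != "DISCARD"
  t <- t[keep, , drop = FALSE]
  excluded <- setdiff(allDrugs, unique(t$drug_id))
  log <- list(read = nRead, kept = nrow(t),
              dropped_unmappable_moa = nRead - nrow(t),
              excluded_drugs = excluded)
  stopifnot(log$kept + log$dropped_unmappable_moa == log$read)
  if (verbose)
    logMsg("parse_drug_targets",
           sprintf("read=%d kept=%d unmappable_moa=%d drugs_excluded=%d",
                   log$read, log$kept, log$dropped_unmappable_moa,
                   length(excluded)))
  DrugSet(t, parseLog = log)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over \code{stats::p.adjust(method = "BH")}: values
#' must lie in [0, 1]; the output is order-aligned with the input, clipped at
#' 1, elementwise no smaller than the input, and monotone in it.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Read a differential-expression (DEG) table
#'
#' Expects tab-separated columns \code{gene}, \code{log2fc}, \code{p} and
#' optionally \code{p_adj}; if \code{p_adj} is absent it is computed with
#' [bhAdjust()] across all rows of the file.
#'
#' @param path path to the DEG TSV.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{p_adj}.
#' @export
readDegTable <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("DEG table lacks required column(s): ", paste(missing, collapse = ", "))
  if (is.null(d$p_adj)) d$p_adj <- bhAdjust(d$p)
  d[, c("gene", "log2fc", "p", "p_adj")]
}

#' Export an explanation subnetwork
#'
#' Writes the union of the edges of a set of scored paths (as returned by
#' [allShortestPaths()]) in SIF, GraphML or plain edge-table TSV format, with
#' per-edge effect/score/multiplicity attributes and per-node role attributes
#' (drug target, disease gene, or path intermediate). Edges shared by several
#' paths are written once, carrying their multiplicity. Output ordering is
#' deterministic (lexicographic by source then target).
#'
#' @param paths nonempty list of scored paths, each a list with elements
#'   \code{nodes} (character) and \code{edges} (data.frame with columns
#'   \code{source}, \code{target}, \code{effect}, \code{score}).
#' @param path output file path. For \code{format = "tsv"} a companion node
#'   table is written next to it with suffix \code{.nodes.tsv}; for
#'   \code{"sif"} roles are implicit in the edge lines.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @param nodeRoles optional named character vector of roles per node; nodes
#'   not named default to \code{"intermediate"}.
#' @return \code{path}, invisibly.
#' @export
exportSubnetwork <- function(paths, path,
                             format = c("sif", "graphml", "tsv"),
                             nodeRoles = NULL) {
  format <- match.arg(format)
  if (!length(paths)) stop("no paths to export")
  allEdges <- do.call(rbind, lapply(paths, function(p) p$edges))
  key <- paste(allEdges$source, allEdges$target, allEdges$effect,
               allEdges$score, sep = "\r")
  mult <- table(key)
  first <- !duplicated(key)
  ed <- allEdges[first, , drop = FALSE]
  ed$multiplicity <- as.integer(mult[key[first]])
  ed <- ed[order(ed$source, ed$target, ed$effect), , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(unlist(lapply(paths, function(p) p$nodes))))
  roles <- rep("intermediate", length(nodes))
  names(roles) <- nodes
  if (!is.null(nodeRoles)) {
    hit <- intersect(names(nodeRoles), nodes)
    roles[hit] <- nodeRoles[hit]
  }
  if (format == "sif") {
    lines <- paste(ed$source, tolower(ed$effect), ed$target, sep = "\t")
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      ed[, c("source", "target", "effect", "score", "multiplicity")],
      directed = TRUE,
      vertices = data.frame(name = nodes, role = unname(roles)))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nodeFile <- paste0(sub("\\.tsv$", "", path), ".nodes.tsv")
    utils::write.table(data.frame(node = nodes, role = unname(roles)),
                       nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
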