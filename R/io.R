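#' Parse a rooted Newick tree with branch lengths
#'
#' Thin, validating wrapper around [ape::read.tree()].  The returned tree is
#' the `phylo` object every other function in the package operates on.
#' Trees must be rooted with unique tip labels and a branch length on every
#' edge; polytomies are rejected by default because the divergence model is
#' defined on a binary tree (an n-tip rooted binary tree has `2n - 1` nodes
#' and `2n - 2` branches).
#'
#' @param text a Newick string (mutually exclusive with `file`).
#' @param file path to a Newick file.
#' @param resolve_polytomies if `TRUE`, multifurcations are resolved
#'   arbitrarily with zero-length branches ([ape::multi2di()]); downstream
#'   code bumps zero lengths to a small epsilon.
#' @return a rooted binary `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:1.5);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL, resolve_polytomies = FALSE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- if (is.null(file)) {
    suppressWarnings(tryCatch(ape::read.tree(text = text),
             error = function(e) stop("malformed Newick: ", conditionMessage(e))))
  } else {
    suppressWarnings(tryCatch(ape::read.tree(file = file),
             error = function(e) stop("malformed Newick in '", file, "': ",
                                      conditionMessage(e))))
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: could not parse a tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("every branch must carry a length")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    # a basal multifurcation in the Newick string shows up in ape as an
    # unrooted tree; treat it as a root polytomy
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    if (!ape::is.rooted(tree) || !ape::is.binary(tree))
      stop("tree could not be resolved to a rooted binary tree")
  }
  tree
}

#' Write a tree with internal nodes labelled by covariation regime
#'
#' Emits Newick text in which every internal node carries the id of the
#' regime its subtending branch belongs to (the root is labelled with the
#' ancestral regime 0), the annotation format used for reporting a fitted
#' set of regimes.
#'
#' @param tree a `phylo` object.
#' @param assignment either a [greedy_search()] / [shift_search()] result,
#'   or an integer vector of regime ids named by node id covering at least
#'   every internal node.
#' @param file optional path; when omitted the Newick string is returned.
#' @return the Newick string, invisibly when `file` is given.
#' @seealso [regimes_from_tree()] for the inverse.
#' @export
write_regime_tree <- function(tree, assignment, file = NULL) {
  if (inherits(assignment, "regime_model"))
    assignment <- node_regimes(tree, assignment$shift_nodes)
  n <- ape::Ntip(tree)
  internal <- seq.int(n + 1L, n + tree$Nnode)
  lab <- assignment[as.character(internal)]
  if (anyNA(lab))
    stop("unassigned internal nodes: ",
         paste(internal[is.na(lab)], collapse = ", "))
  tree$node.label <- as.character(unname(lab))
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Per-node regime ids implied by a set of shift nodes
#'
#' The regime of a node is the regime of its subtending branch (the root
#' takes regime 0).  Shift nodes therefore carry their *parent* regime —
#' the shift takes effect on the branches inside the clade.
#'
#' @inheritParams regime_assignment
#' @return integer vector named by node id, covering all `2n - 1` nodes.
#' @export
node_regimes <- function(tree, shift_nodes = integer(0)) {
  branch_reg <- regime_assignment(tree, shift_nodes)
  root <- .root_node(tree)
  out <- c(stats::setNames(0L, root), branch_reg)
  out[order(as.integer(names(out)))]
}

#' Read regime labels back from an annotated tree
#'
#' @param tree a `phylo` with integer `node.label`s as written by
#'   [write_regime_tree()].
#' @return integer vector of regime ids named by internal node id.
#' @export
regimes_from_tree <- function(tree) {
  if (is.null(tree$node.label))
    stop("tree carries no internal node labels")
  n <- ape::Ntip(tree)
  stats::setNames(as.integer(tree$node.label), seq.int(n + 1L, n + tree$Nnode))
}

#' Build a species-by-trait matrix from long-format measurements
#'
#' Replicate measurements of a trait are averaged first and the mean is then
#' natural-log transformed, so all traits end up on a common (log) scale.
#' Species missing any trait are dropped with a warning rather than imputed.
#'
#' @param records data frame with columns `species`, `trait`, `value`
#'   (strictly positive measurements).
#' @return numeric matrix, species in rows (rownames), traits in columns.
#' @examples
#' rec <- data.frame(species = c("A", "A", "B"),
#'                   trait = "leaf_length", value = c(2, 4, 10))
#' prepare_traits(rec)   # A row is log(3)
#' @export
prepare_traits <- function(records) {
  need <- c("species", "trait", "value")
  if (!all(need %in% names(records)))
    stop("`records` must have columns species, trait, value")
  if (any(!is.finite(records$value)) || any(records$value <= 0))
    stop("measurements must be strictly positive (log transform undefined)")
  agg <- stats::aggregate(value ~ species + trait, data = records, FUN = mean)
  species <- sort(unique(agg$species))
  traits <- sort(unique(agg$trait))
  X <- matrix(NA_real_, length(species), length(traits),
              dimnames = list(species, traits))
  X[cbind(match(agg$species, species), match(agg$trait, traits))] <- agg$value
  incomplete <- rownames(X)[apply(X, 1, anyNA)]
  if (length(incomplete)) {
    warning("excluding species with missing traits: ",
            paste(incomplete, collapse = ", "))
    X <- X[setdiff(rownames(X), incomplete), , drop = FALSE]
  }
  if (!nrow(X)) stop("no species with complete trait records")
  log(X)
}

#' Read a wide species-by-trait table
#'
#' @param file CSV/TSV with a header `species,trait1,...,traitk`; the
#'   delimiter is sniffed from the header line.
#' @return numeric matrix with species rownames.
#' @export
read_trait_table <- function(file) {
  header <- readLines(file, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.csv(file, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need a species column and at least two traits")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df[[1]])
  if (anyDuplicated(rownames(X))) stop("duplicate species in trait table")
  X
}

#' Principal component summary of the trait space
#'
#' PCA of the (log-scale) trait matrix on the covariance scale: columns are
#' centred but not re-standardised, since logging already places traits on a
#' common scale.  Set `correlation = TRUE` for correlation-based PCA.
#'
#' @param X species-by-trait numeric matrix with at least two rows and
#'   columns.
#' @param correlation standardise columns to unit variance first?
#' @return list with `scores` (species by component, zero column means) and
#'   `proportion_variance` (descending, sums to 1).
#' @export
pca_summary <- function(X, correlation = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 species and 2 traits")
  if (all(apply(X, 2, stats::sd) == 0))
    stop("constant trait matrix: no variance to decompose")
  if (correlation && any(apply(X, 2, stats::sd) == 0))
    stop("constant trait column: correlation PCA undefined")
  fit <- stats::prcomp(X, center = TRUE, scale. = correlation)
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, proportion_variance = prop)
}
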