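#' Parse a Newick string into a validated phylogeny
#'
#' Accepts the standard Newick dialect (tip labels, branch lengths, optional
#' internal labels; square-bracket comments are stripped). The returned tree
#' is an [ape::read.tree()] `"phylo"` object that has passed
#' [validate_phylo()]: unique nonempty tip labels, nonnegative branch lengths
#' and a single root.
#'
#' @param text a Newick string (a single tree, terminated by `;`).
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):2,C:3);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("\\[[^]]*\\]", "", text)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  last_open <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      last_open <- i
    } else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at character offset ", i)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed Newick: unmatched '(' at character offset ", last_open)
  }
  if (!grepl(";", text)) {
    stop("malformed Newick: no terminating ';' found")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick: could not be parsed")
  validate_phylo(tree)
}

#' Serialize a phylogeny to Newick
#'
#' Round-trips with [parse_newick()] up to whitespace and numeric formatting.
#'
#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  validate_phylo(tree)
  ape::write.tree(tree, digits = digits)
}

#' Validate phylogeny invariants
#'
#' Checks that `tree` is a rooted `"phylo"` with at least two tips, unique
#' nonempty tip labels, branch lengths present and nonnegative, and exactly
#' one root. Returns the tree invisibly so it can be used in pipelines.
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- ape::Ntip(tree)
  if (n < 2) stop("tree must have at least 2 tips")
  lab <- tree$tip.label
  if (anyDuplicated(lab)) {
    stop("duplicate tip labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (any(!nzchar(lab))) stop("empty tip labels are not allowed")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  # every non-root node has exactly one parent; exactly one root
  parents <- tabulate(tree$edge[, 2], nbins = n + tree$Nnode)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1) stop("tree must have exactly one root")
  if (any(parents > 1)) stop("a node has more than one parent")
  invisible(tree)
}

#' Root-to-node path lengths
#'
#' @param tree a `"phylo"` object.
#' @return numeric vector of root-to-node distances for all nodes
#'   (tips `1..n`, then internal nodes), in millions of years if the branch
#'   lengths are so calibrated.
#' @export
node_depths <- function(tree) {
  validate_phylo(tree)
  ape::node.depth.edgelength(tree)
}

#' Test whether a tree is ultrametric (within a relative tolerance)
#'
#' Time-calibrated consensus trees carry rounding, so the check uses the
#' relative spread of root-to-tip depths: `(max - min) / max <= tol`.
#'
#' @param tree a `"phylo"` object.
#' @param tol relative tolerance (default `1e-6`).
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol * max(d)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Builds the among-species covariance scaffold `C` with
#' `C[i, j]` = shared root-to-MRCA path length of tips `i` and `j`, and
#' `C[i, i]` = root-to-tip path length. Computed by accumulating each edge
#' length over the block of its descendant tips, which is exactly the
#' path-sum definition.
#'
#' @param tree a `"phylo"` object.
#' @return a symmetric positive semi-definite matrix with species dimnames
#'   and attributes `model = "bm"` and `params` (an empty parameter record).
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  # descendant tips per node
  desc <- vector("list", m)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[e, 2]]]
    C[tips, tips] <- C[tips, tips] + tree$edge.length[e]
  }
  attr(C, "model") <- "bm"
  attr(C, "params") <- list()
  C
}

#' Transform a Brownian covariance under a named evolutionary model
#'
#' Applies Pagel's lambda, the star-phylogeny collapse, a fixed-root
#' Ornstein-Uhlenbeck transform, or the Early-Burst (ACDC, r <= 0) transform
#' to a Brownian-motion covariance matrix `C`:
#'
#' * `lambda`: off-diagonals multiplied by `lambda` (`lambda` in `[0, 1]`);
#'   the diagonal is unchanged. `lambda = 1` is the identity.
#' * `star`: `diag(C)` - no shared history.
#' * `ou` (scalar `alpha > 0`, fixed root, ultrametric trees only):
#'   `C'[i,j] = exp(-alpha * (ti + tj - 2 tij)) * (1 - exp(-2 alpha tij)) / (2 alpha)`
#'   with `tij = C[i, j]` the shared path length and `ti = C[i, i]`.
#' * `eb` (`r <= 0`): `C'[i,j] = (exp(r * tij) - 1) / r`, continuous at
#'   `r = 0` where it equals the Brownian `tij`.
#'
#' @param C Brownian covariance from [phylo_vcv()] (or any matrix with the
#'   same path-sum semantics).
#' @param model one of `"bm"`, `"lambda"`, `"star"`, `"ou"`, `"eb"`.
#' @param params list with the model's parameter: `lambda`, `alpha` or `r`.
#' @return transformed covariance matrix (symmetric PSD) with updated
#'   `model`/`params` attributes.
#' @export
transform_covariance <- function(C, model = c("bm", "lambda", "star", "ou", "eb"),
                                 params = list()) {
  model <- match.arg(model)
  out <- switch(model,
    bm = C,
    lambda = {
      lam <- params$lambda
      if (is.null(lam) || lam < 0 || lam > 1) {
        stop("lambda must be in [0, 1]")
      }
      d <- diag(C)
      Cp <- C * lam
      diag(Cp) <- d
      Cp
    },
    star = diag(diag(C), nrow = nrow(C)),
    ou = {
      a <- params$alpha
      if (is.null(a) || a <= 0) stop("alpha must be > 0")
      ti <- diag(C)
      if ((max(ti) - min(ti)) > 1e-6 * max(ti)) {
        stop("OU transform requires an ultrametric tree ",
             "(unequal root-to-tip depths)")
      }
      Touter <- outer(ti, ti, "+")
      exp(-a * (Touter - 2 * C)) * (1 - exp(-2 * a * C)) / (2 * a)
    },
    eb = {
      r <- params$r
      if (is.null(r) || r > 0) stop("r must be <= 0")
      if (r == 0) C else matrix(expm1(r * C) / r, nrow(C), ncol(C),
                                dimnames = dimnames(C))
    }
  )
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(C)
  attr(out, "model") <- model
  attr(out, "params") <- params
  out
}

#' Align a tree with a species set
#'
#' Tip labels and the requested species are matched after
#' [normalize_species()] normalization. Species absent from the tree are a
#' hard error (silent dropping hides data loss); tips absent from the species
#' set are pruned with a warning. The returned tree's tip labels are replaced
#' by the matching entries of `species` so downstream joins are exact.
#'
#' @param tree a `"phylo"` object.
#' @param species character vector of species names to keep.
#' @return pruned `"phylo"` whose tip labels are exactly `species` (in tree
#'   order).
#' @export
match_tree_traits <- function(tree, species) {
  validate_phylo(tree)
  key_tree <- normalize_species(tree$tip.label)
  key_sp <- normalize_species(species)
  if (anyDuplicated(key_sp)) {
    stop("duplicate species in trait data: ",
         paste(species[duplicated(key_sp)], collapse = ", "))
  }
  missing <- species[!(key_sp %in% key_tree)]
  if (length(missing) > 0) {
    stop("species missing from the tree: ", paste(missing, collapse = ", "))
  }
  extra <- tree$tip.label[!(key_tree %in% key_sp)]
  if (length(extra) > 0) {
    warning("pruning ", length(extra), " tree tip(s) not in the trait data: ",
            paste(extra, collapse = ", "))
    tree <- ape::drop.tip(tree, extra)
  }
  tree$tip.label <- species[match(normalize_species(tree$tip.label), key_sp)]
  validate_phylo(tree)
}

#' Tree summary: tip count, depth, ultrametricity
#'
#' @param tree a `"phylo"` object.
#' @return list with `n_tips`, `n_internal`, `depth` (max root-to-tip path)
#'   and `ultrametric`.
#' @export
tree_info <- function(tree) {
  validate_phylo(tree)
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  list(n_tips = ape::Ntip(tree), n_internal = tree$Nnode,
       depth = max(d), ultrametric = is_ultrametric(tree))
}
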