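# Kaiser-criterion PCA with cABC variable contributions ------------------

#' PCA structure scan with Kaiser criterion and cABC variable importance
#'
#' Eigen-decomposes the feature correlation matrix, retains the components
#' with eigenvalue strictly greater than 1 (Kaiser criterion), and scores
#' each feature's contribution to the retained structure as the sum over
#' retained components of its squared loading weighted by the component's
#' explained-variance fraction. The cABC category-A features of this
#' importance vector are the variables that carry the retained structure.
#'
#' @param ds A standardized [lipid_dataset] with at least 3 samples.
#' @return A `lipid_pca`: list with `eigenvalues`, `retained` (indices),
#'   `explained_fraction`, `loadings` (feature x component), `importance`
#'   (named vector) and `important_features` (cABC category A).
#' @export
pca_structure <- function(ds) {
  if (nrow(ds$values) < 3L) {
    stop_lipidmoe("PCA needs at least 3 samples", "lipidmoe_size_error")
  }
  if (!ds$standardized) {
    stop_lipidmoe("pca_structure expects a z-standardized dataset",
                  "lipidmoe_contract_error")
  }
  cm <- cor(ds$values)
  eig <- eigen(cm, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  d <- ncol(ds$values)
  retained <- which(lambda > 1)
  loadings <- eig$vectors %*% diag(sqrt(lambda), nrow = d)
  dimnames(loadings) <- list(colnames(ds$values),
                             paste0("PC", seq_len(d)))
  var_frac <- lambda / d
  if (length(retained)) {
    importance <- drop(loadings[, retained, drop = FALSE]^2 %*%
                         var_frac[retained])
  } else {
    importance <- setNames(rep(0, d), colnames(ds$values))
  }
  important_features <- if (length(retained) && any(importance > 0)) {
    abc_members(cabc_categorize(importance), "A")
  } else {
    character()
  }
  structure(
    list(eigenvalues = lambda, retained = retained,
         explained_fraction = sum(var_frac[retained]),
         loadings = loadings, importance = importance,
         important_features = important_features),
    class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf(
    "<lipid_pca> %d components with eigenvalue > 1 explaining %.2f%% of variance\n",
    length(x$retained), 100 * x$explained_fraction))
  cat(sprintf("  %d category-A contributing features\n",
              length(x$important_features)))
  invisible(x)
}

#' @export
tidy.lipid_pca <- function(x, ...) {
  tibble::tibble(
    feature = names(x$importance),
    importance = unname(x$importance),
    important = names(x$importance) %in% x$important_features)
}

#' @export
glance.lipid_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$eigenvalues),
                 n_retained = length(x$retained),
                 explained_fraction = x$explained_fraction,
                 n_important_features = length(x$important_features))
}
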