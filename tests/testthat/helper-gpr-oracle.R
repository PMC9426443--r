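# Independent random-GPR oracle shared by the unit and acceptance suites.
# Trees are generated as explicit nested structures, rendered to fully
# parenthesized rule text, and evaluated by this file's own min/sum
# recursion -- none of which goes through the package's parser or evaluator.

random_tree <- function(depth, genes) {
  if (depth == 0 || runif(1) < 0.35) {
    return(list(kind = "leaf", gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  n_kids <- sample(2:3, 1)
  list(kind = op,
       kids = lapply(seq_len(n_kids), function(i) {
         random_tree(depth - 1, genes)
       }))
}

tree_text <- function(node) {
  if (node$kind == "leaf") return(node$gene)
  paste0("(", paste(vapply(node$kids, tree_text, character(1)),
                    collapse = paste0(" ", node$kind, " ")), ")")
}

tree_value <- function(node, vals) {
  if (node$kind == "leaf") return(vals[[node$gene]])
  kid_vals <- vapply(node$kids, tree_value, numeric(1), vals = vals)
  if (node$kind == "and") min(kid_vals) else sum(kid_vals)
}
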