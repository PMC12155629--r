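# union of neighbor node names of a vertex set
.neighbor_names <- function(g, vs) {
  al <- igraph::adjacent_vertices(g, vs)
  unique(unlist(lapply(al, names), use.names = FALSE))
}
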