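# Small web builders used across the suite.

chain_web <- function(n = 3L, id = "chain", prefix = letters[seq_len(n)]) {
  food_web(prefix, cbind(prefix[-n], prefix[-1L]), id = id)
}

star3_web <- function(id = "star3", prefix = "s") {
  centre <- paste0(prefix, "0")
  leaves <- paste0(prefix, 1:3)
  food_web(c(centre, leaves), cbind(centre, leaves), id = id)
}

# identity self-alignment of a web
identity_alignment <- function(web) {
  web_alignment(web$species, web$species, seq_along(web$species),
                web$id, web$id)
}

# motif-rich 6-link test backbone: omnivory triangle + chain + second apex
rich_backbone <- function(id = "core") {
  food_web(sprintf("b%d", 1:5),
           rbind(c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
                 c("b3", "b4"), c("b4", "b5"), c("b2", "b5")), id = id)
}
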