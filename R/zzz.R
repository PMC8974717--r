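.onLoad <- function(libname, pkgname) {
  register_season_method("percentage",
                         function(series, ...)
                           define_season_percentage(series, ...))
}
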