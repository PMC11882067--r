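# Shared expensive objects: one prepared model (life table + survival fits)
# and one base-case run reused across test files.
CFG <- base_case_config()
PREP <- prepare_model(CFG)
BC <- run_cea(CFG, prepared = PREP)
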