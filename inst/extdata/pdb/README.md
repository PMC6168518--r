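Place local copies of the deposited crystal structures here as
`4M1M.pdb`, `4M2S.pdb`, `4M2T.pdb` (e.g. downloaded from
https://files.rcsb.org/download/4M1M.pdb) to enable the
crystal-geometry acceptance checks and the corresponding entries in
`scripts/acceptance.R`. No structure files are bundled with the package.
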