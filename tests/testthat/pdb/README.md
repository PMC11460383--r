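Deposited PDB entries used by the published-constant and protein-band
tests. Not distributed with the package; fetch them here to enable those
tests:

    for id in 2lyz 1gip 1btc 1a34 3v03 1i10 6z6u; do
      curl -sO https://files.rcsb.org/download/${id^^}.pdb
      mv ${id^^}.pdb ${id}.pdb
    done
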