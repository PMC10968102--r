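>capitellacin ss=5-18,9-14 source=reconstructed-from-published-residue-identities
SPRVCIRVCRNGVCYRRCWG
>tachyplesin-1 ss=3-16,7-12 amide=1 source=external-literature-fixture-unverified
KWCFRVCYRGICYRRCR
>thanatin ss=11-18 source=external-literature-fixture-unverified
GSKKPVPIIYCNRRTGKCQRM
>melittin amide=1 source=external-literature-fixture-unverified
GIGAVLKVLTTGLPALISWIKRKRQQ
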