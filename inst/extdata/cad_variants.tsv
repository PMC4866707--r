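id	sequence	fold_activation
GCN4_81_100	MKTVLPIPELDDAVVESFFSSGSGSGS	1
cAD-like07	MKTVLPIPELDDAVWESLFSSGSGSGS	7
cAD-like96	MKTVLPIPELDDAWWWWLFWSGSGSGS	96
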