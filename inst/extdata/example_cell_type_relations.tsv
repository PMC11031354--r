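child	parent	relation
ciliated columnar cell of tracheobronchial tree	ciliated cell	parent
ciliated epithelial cell	ciliated cell	parent
lung ciliated cell	ciliated cell	parent
ciliated epithelial cell	epithelial cell	parent
blood vessel endothelial cell	vein endothelial cell	synonym
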