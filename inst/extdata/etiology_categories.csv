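etiology,category
TBI,Traumatic brain injury
TBI (Op),Traumatic brain injury
"TBI, IS",Traumatic brain injury
IS,Ischemic stroke
IS (RA),Ruptured aneurism
HS,Hemorrhagic stroke
HS (RA),Ruptured aneurism
"IS, IVH",Intraventricular hemorrhage
Anoxia,Anoxia
Inf,Infection
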