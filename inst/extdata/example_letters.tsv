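id	complaint	label
EX-R51	We would be grateful if you could review this 56-year-old gentleman. He was admitted on 27-11-18 after falling down the stairs. Preceding dizziness where he felt he would pass out but did not lose consciousness. 2 weeks ago, states developed sudden onset headache - vice-like, severity at start 8-10. Not positional. Right eyes have tunnel vision. On examination had reduced abduction right eye and diplopia. The case was discussed with Dr xxx who suggested MRI. The MRI report is as below and suggests a neurology review.	R51
EX-I63	Mrs XXXX was admitted with new left arm weakness on a background of muscular dystrophy. A CT showed no intracranial acute abnormality. There was an unexpected finding of bifrontal disproportionate apparent volume loss, with a lack of transverse veins which could represent inconspicuous subdural haematomas - for which a follow-up CT scan in 2 weeks has been requested. Our impression is of muscular dystrophy progression.	I63
EX-M54	History of leg pain and numbness. This lady related a history of 2 years or so of right leg numbness secondary to chronic back pain. She related a 2-week history of left-sided numbness in the thighs and worsening of her back pain. Examination reveals that she has decreased sensation in the left L4-5 nerve route distribution on the medial aspect of the left calf and dorsal aspect of the left foot. The plantar sensation is normal. Power to L4-5 and S1 is normal although she is unable to flex her hips fully and cannot perform an active SLR.	M54
EX-G40	We would be grateful for your assessment of this 47-year-old lady. She has known Epilepsy post-head-injury ten years ago and has not had a seizure in 3 years. She presented last week with 3 x tonic-colonic seizures, each of which terminated with Diazepam. She usually takes Carbamazepine 400mg BD, however, had not been taking this for the previous few weeks. She still has a residual left-sided weakness. Power in her left leg remains at 1-2-5, and the left arm-hand at 2-3-5. I discussed her with the on-call neurologist on Friday who advised starting her back on her normal medication with 7-10 days of Clobazam to cover. She is still very fatigued and sleeping much of the day.	G40
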