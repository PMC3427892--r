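scale,item_id,label,n,difficulty,observed_errors,expected_errors,H,z
cognitive,hammer,Describing the use of a hammer,15022,0.024,486,2289.2,0.79,73.2
cognitive,elbow,Naming elbow,15022,0.032,1105,2933.0,0.62,64.7
cognitive,point2,Pointing to window and then to door,15022,0.040,1264,3457.8,0.63,69.9
cognitive,store,Locating nearest store,15022,0.059,1679,4423.4,0.62,73.1
cognitive,season,Orientation to season,15022,0.062,1793,4523.7,0.60,71.3
cognitive,dayweek,Orientation to day of the week,15022,0.100,2210,5328.3,0.59,66.2
cognitive,recall3,Delayed recall of three words,15022,0.283,2597,7570.0,0.66,62.1
cognitive,whole_scale,Whole scale,15022,NA,5567,15262.7,0.64,116.3
informant,put_things,Often forgets where she/he had put things,14922,0.523,2334,7039.5,0.67,90.4
informant,mental_decline,General decline in mental functioning,14922,0.868,1833,5459.0,0.66,101.4
informant,think_reason,Change in ability to think and reason,14922,0.908,1638,5297.7,0.69,117.2
informant,forget_yesterday,Sometimes forgets what happened the day before,14922,0.913,2143,7117.2,0.70,124.7
informant,forget_where,Sometimes forgets where she/he is,14922,0.968,1201,4291.7,0.72,108.3
informant,dressing,Difficulty dressing,14922,0.982,1105,3605.7,0.69,81.2
informant,whole_scale,Whole scale,14922,NA,5127,16405.4,0.69,174.9
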